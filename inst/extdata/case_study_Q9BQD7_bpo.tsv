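truth	GO:0044238,GO:0006479,GO:0032259,GO:0044237,GO:0018193,GO:0036211,GO:0008152,GO:0009987,GO:0008213,GO:0043414,GO:0043412,GO:0006807,GO:0018205,GO:0006464,GO:0044267,GO:0071704,GO:0019538,GO:1901564,GO:0044260,GO:0043170,GO:0018022,GO:0018023
blast-knn
lr-interpro	GO:0006139,GO:0006725,GO:0006807,GO:0008152,GO:0009987,GO:0032259,GO:0034641,GO:0043170,GO:0043412,GO:0043414,GO:0044237,GO:0044238,GO:0044260,GO:0046483,GO:0065007,GO:0071704,GO:0090304,GO:1901360,GO:1901564
net-knn	GO:0006139,GO:0006412,GO:0006464,GO:0006479,GO:0006518,GO:0006725,GO:0006807,GO:0008152,GO:0008213,GO:0009058,GO:0009059,GO:0009987,GO:0010467,GO:0010468,GO:0016070,GO:0019222,GO:0019538,GO:0032259,GO:0034641,GO:0034645,GO:0036211,GO:0043043,GO:0043170,GO:0043412,GO:0043414,GO:0043603,GO:0043604,GO:0044237,GO:0044238,GO:0044249,GO:0044260,GO:0044267,GO:0044271,GO:0046483,GO:0048519,GO:0050789,GO:0050794,GO:0060255,GO:0065007,GO:0071704,GO:0090304,GO:1901360,GO:1901564,GO:1901566,GO:1901576
deepgocnn	GO:0044238,GO:1901564,GO:0008152,GO:0043170,GO:0044237,GO:0006807,GO:0009987,GO:0071704,GO:0050896,GO:0050794,GO:0050789,GO:0031323,GO:0048519,GO:0065007,GO:0019222,GO:0080090,GO:0060255,GO:1901576,GO:0009058,GO:0044249
deepgoplus	GO:0009987,GO:0008152,GO:0071704,GO:0044237,GO:0065007
gcn	GO:0006464,GO:0006479,GO:0006807,GO:0008152,GO:0008213,GO:0009058,GO:0009987,GO:0019538,GO:0032259,GO:0034641,GO:0036211,GO:0043170,GO:0043412,GO:0043414,GO:0044237,GO:0044238,GO:0044249,GO:0044260,GO:0044267,GO:0050789,GO:0065007,GO:0071704,GO:0071840,GO:1901564,GO:1901576
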