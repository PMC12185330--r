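disorder,cases,cohort_n
MD,333018,1886190
AD,372448,1886190
OCD,24491,1886190
AN,9457,1886190
BN,5957,1886190
DUD,106005,1886190
AUD,71554,1886190
ADHD,62667,1886190
BD,27664,1886190
SZ,3805,1886190
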