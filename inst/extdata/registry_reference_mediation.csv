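disorder,total,direct,indirect,ind_iq,ind_res
DUD,-0.171,-0.079,-0.092,-0.052,-0.041
AUD,-0.182,-0.089,-0.094,-0.062,-0.032
ADHD,-0.109,-0.029,-0.080,-0.041,-0.038
MD,-0.053,-0.014,-0.039,-0.005,-0.035
AD,-0.053,0.000,-0.053,-0.021,-0.032
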