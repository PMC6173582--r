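source,target,count
AS,dorsal_BWM,68
AS,VD,66
AS,other,10
A,ventral_BWM,225
A,dorsal_BWM,111
B,ventral_BWM,228
B,dorsal_BWM,58
VA,DD,180
VB,DD,194
DA,DD,8
DB,DD,29
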