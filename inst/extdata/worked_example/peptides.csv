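sequence,activity,ec50_um,source_id
VWK,ace inhibitor,2,WE1
IPP,ace inhibitor,5,WE2
KP,ace inhibitor,,WE3
GP,dipeptidyl peptidase iv inhibitor,,WE4
PG,dipeptidyl peptidase iv inhibitor,,WE5
AH,antioxidative,12.5,WE6
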