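sequence,activity,ec50_um,source_id
VPP,ACE inhibitor,9,SYNDB001
IPP,ACE inhibitor,5,SYNDB002
VW,ACE inhibitor,1.6,SYNDB003
IW,ACE inhibitor,0.7,SYNDB004
IY,ACE inhibitor,3.7,SYNDB005
AW,ACE inhibitor,10,SYNDB006
FY,ACE inhibitor,25,SYNDB007
GF,ACE inhibitor,,SYNDB008
IPI,dipeptidyl peptidase IV inhibitor,3.5,SYNDB009
VPL,dipeptidyl peptidase IV inhibitor,16,SYNDB010
IPA,dipeptidyl peptidase IV inhibitor,49,SYNDB011
WV,dipeptidyl peptidase IV inhibitor,,SYNDB012
GP,dipeptidyl peptidase IV inhibitor,,SYNDB013
VA,dipeptidyl peptidase IV inhibitor,,SYNDB014
LY,antioxidative,,SYNDB015
EL,antioxidative,,SYNDB016
AH,antioxidative,,SYNDB017
HL,antioxidative,,SYNDB018
LA,activating ubiquitin-mediated proteolysis,,SYNDB019
AL,activating ubiquitin-mediated proteolysis,,SYNDB020
DY,regulating,,SYNDB021
YP,regulating,,SYNDB022
PGP,antithrombotic,,SYNDB023
GPR,antithrombotic,,SYNDB024
PG,antiamnestic,,SYNDB025
VP,antiamnestic,,SYNDB026
EE,stimulating,,SYNDB027
EK,stimulating,,SYNDB028
GLF,immunomodulating,,SYNDB029
YG,immunomodulating,,SYNDB030
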