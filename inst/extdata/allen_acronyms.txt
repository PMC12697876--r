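ACA
ACAd
ACAv
ACB
AD
AI
AId
AIp
AIv
AMB
AOB
AON
APN
ARH
AUD
AUDd
AUDp
AUDv
AV
BLA
BMA
BST
CA1
CA2
CA3
CEA
CLA
CLI
COA
CP
CS
CUN
DCO
DG
DMH
DN
DR
ECT
ENT
ENTl
ENTm
EP
EPd
EPv
FRP
FS
GPe
GPi
GU
HPF
HY
IA
IC
ILA
IO
IP
LA
LD
LGd
LGv
LH
LHA
LP
LPO
LS
LSc
LSr
MA
MB
MD
MEA
MG
MH
MM
MOB
MOp
MOs
MPN
MPO
MRN
MS
MV
NDB
NLL
NTS
OLF
ORB
ORBl
ORBm
ORBvl
OT
PAA
PAG
PAL
PAR
PB
PCG
PERI
PF
PG
PH
PIR
PL
PO
POST
PP
PPN
PRE
PRNc
PRNr
PSV
PT
PVH
PVT
RE
RN
RSP
RSPagl
RSPd
RSPv
RT
SC
SCH
SCm
SCs
SI
SMT
SNc
SNr
SO
SPF
SS
SSp
SSs
STN
STR
SUB
SUM
TEa
TH
TR
TRN
TT
TU
VAL
VCO
VII
VISC
VISa
VISal
VISam
VISl
VISp
VISpm
VM
VMH
VPL
VPM
VTA
ZI
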