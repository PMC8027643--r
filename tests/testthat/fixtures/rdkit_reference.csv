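seq,MW,tPSA,Fsp3,cLogP,HBA,HBD,NAR,NRB,formula
A,89.094,63.32,0.666667,-0.5818,3,3,0,1,C3H7NO2
C,121.161,63.32,0.666667,-0.6719,3,3,0,2,C3H7NO2S
D,133.103,100.62,0.5,-1.127,5,4,0,3,C4H7NO4
E,147.13,100.62,0.6,-0.7369,5,4,0,4,C5H9NO4
F,165.192,63.32,0.222222,0.641,3,3,1,3,C9H11NO2
G,75.067,63.32,0.5,-0.9703,3,3,0,1,C2H5NO2
H,155.157,92.0,0.333333,-0.6359,5,4,1,3,C6H9N3O2
I,131.175,63.32,0.833333,0.4444,3,3,0,3,C6H13NO2
K,146.19,89.34,0.833333,-0.4727,4,5,0,5,C6H14N2O2
L,131.175,63.32,0.833333,0.4444,3,3,0,3,C6H13NO2
M,149.215,63.32,0.8,0.1514,3,3,0,4,C5H11NO2S
N,132.119,106.41,0.5,-1.7263,5,5,0,3,C4H8N2O3
P,115.132,49.33,0.8,-0.177,3,2,0,1,C5H9NO2
Q,146.146,106.41,0.6,-1.3362,5,5,0,4,C5H10N2O3
R,174.204,125.22,0.666667,-1.3384,6,7,0,5,C6H14N4O2
S,105.093,83.55,0.666667,-1.6094,4,4,0,2,C3H7NO3
T,119.12,83.55,0.75,-1.2209,4,4,0,2,C4H9NO3
V,117.148,63.32,0.8,0.0543,3,3,0,2,C5H11NO2
W,204.229,79.11,0.181818,1.1223,4,4,2,3,C11H12N2O2
Y,181.191,83.55,0.222222,0.3466,4,4,1,3,C9H11NO3
GAG,203.198,121.52,0.571429,-2.3494,7,5,0,5,C7H13N3O4
GCG,235.265,121.52,0.571429,-2.4395,7,5,0,6,C7H13N3O4S
GDG,247.207,158.82,0.5,-2.8946,9,6,0,7,C8H13N3O6
GEG,261.234,158.82,0.555556,-2.5045,9,6,0,8,C9H15N3O6
GFG,279.296,121.52,0.307692,-1.1266,7,5,1,7,C13H17N3O4
GGG,189.171,121.52,0.5,-2.7379,7,5,0,5,C6H11N3O4
GHG,269.261,150.2,0.4,-2.4035,9,6,1,7,C10H15N5O4
GIG,245.279,121.52,0.7,-1.3232,7,5,0,7,C10H19N3O4
GKG,260.294,147.54,0.7,-2.2403,8,7,0,9,C10H20N4O4
GLG,245.279,121.52,0.7,-1.3232,7,5,0,7,C10H19N3O4
GMG,263.319,121.52,0.666667,-1.6162,7,5,0,8,C9H17N3O4S
GNG,246.223,164.61,0.5,-3.4939,9,7,0,7,C8H14N4O5
GPG,229.236,112.73,0.666667,-1.8631,7,4,0,4,C9H15N3O4
GQG,260.25,164.61,0.555556,-3.1038,9,7,0,8,C9H16N4O5
GRG,288.308,183.42,0.6,-3.106,10,9,0,9,C10H20N6O4
GSG,219.197,141.75,0.571429,-3.377,8,6,0,6,C7H13N3O5
GTG,233.224,141.75,0.625,-2.9885,8,6,0,6,C8H15N3O5
GVG,231.252,121.52,0.666667,-1.7133,7,5,0,6,C9H17N3O4
GWG,318.333,137.31,0.266667,-0.6453,8,6,2,7,C15H18N4O4
GYG,295.295,141.75,0.307692,-1.421,8,6,1,7,C13H17N3O5
EAK,346.384,184.84,0.714286,-1.6184,10,8,0,12,C14H26N4O6
IIF,391.512,121.52,0.571429,1.7028,7,5,1,11,C21H33N3O4
EVD,361.351,196.12,0.642857,-1.6366,11,7,0,11,C14H23N3O8
WQC,435.506,180.4,0.368421,-0.7128,10,8,2,11,C19H25N5O5S
ADH,341.324,187.5,0.461538,-2.1717,11,7,1,9,C13H19N5O6
ITY,395.456,161.98,0.526316,-0.2569,9,7,1,10,C19H29N3O6
AVH,325.369,150.2,0.571429,-0.9904,9,6,1,8,C14H23N5O4
VQI,358.439,164.61,0.75,-0.6645,9,7,0,11,C16H30N4O5
RWK,488.593,225.23,0.478261,-0.5158,12,12,2,15,C23H36N8O4
AGQ,274.277,164.61,0.6,-2.7153,9,7,0,8,C10H18N4O5
MKF,424.567,147.54,0.55,0.4927,8,7,1,14,C20H32N4O4S
HME,415.472,187.5,0.5625,-1.0484,11,7,1,13,C16H25N5O6S
DPE,359.335,187.33,0.642857,-1.7864,11,6,0,9,C14H21N3O8
NNY,409.399,227.93,0.352941,-2.933,12,10,1,11,C17H23N5O7
KCR,405.525,209.44,0.733333,-2.31,11,11,0,14,C15H31N7O4S
VEP,343.38,150.03,0.733333,-0.6051,9,5,0,8,C15H25N3O6
DVL,345.396,158.82,0.733333,-0.4553,9,6,0,10,C15H27N3O6
YNW,481.509,200.63,0.25,-0.0844,11,9,3,11,C24H27N5O6
HDC,373.391,187.5,0.461538,-2.2618,11,7,1,10,C13H19N5O6S
ILD,359.423,158.82,0.75,-0.0652,9,6,0,11,C16H29N3O6
GG,132.119,92.42,0.5,-1.8541,5,4,0,3,C4H8N2O3
AAA,231.252,121.52,0.666667,-1.5724,7,5,0,5,C9H17N3O4
GGGGG,303.275,179.72,0.5,-4.5055,11,7,0,9,C10H17N5O6
FWH,488.548,165.99,0.230769,1.3004,10,7,4,11,C26H28N6O4
RRRRR,798.96,489.22,0.666667,-6.3462,26,27,0,29,C30H62N20O6
KRKRKRKRKR,1439.835,764.82,0.75,-8.2771,41,42,0,59,C60H122N30O11
GALFLGFLGAAG,1093.294,383.42,0.54717,-2.0599,25,14,2,33,C53H80N12O13
PPP,309.366,89.95,0.8,-0.195,7,2,0,3,C15H23N3O4
WWCM,624.789,182.2,0.333333,1.9836,11,8,4,15,C30H36N6O5S2
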