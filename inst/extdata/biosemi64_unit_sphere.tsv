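# BioSemi 64-channel layout (10-20 family), idealized spherical positions
# unit-sphere directions in the head frame (+x right ear, +y nasion, +z up);
# scale radially by the head radius to obtain scalp coordinates
label	x	y	z
Fp1	-0.3088287496	0.9504771584	-0.0348994967
AF7	-0.5874271894	0.8085241631	-0.0348994967
AF3	-0.4062467470	0.8711989604	0.2756373558
F1	-0.2869652992	0.7102640395	0.6427876097
F3	-0.5450074458	0.6730281451	0.5000000000
F5	-0.7289934749	0.6337043597	0.2588190451
F7	-0.8085241631	0.5874271894	-0.0348994967
FT7	-0.9504771584	0.3088287496	-0.0348994967
FC5	-0.8878877481	0.3408281736	0.3090169944
FC3	-0.6763770971	0.3596360819	0.6427876097
FC1	-0.3747095052	0.3747095052	0.8480480962
C1	-0.3907311285	-0.0000000000	0.9205048535
C3	-0.7193398003	-0.0000000000	0.6946583705
C5	-0.9335804265	-0.0000000000	0.3583679495
T7	-0.9993908270	-0.0000000000	-0.0348994967
TP7	-0.9504771584	-0.3088287496	-0.0348994967
CP5	-0.8878877481	-0.3408281736	0.3090169944
CP3	-0.6763770971	-0.3596360819	0.6427876097
CP1	-0.3747095052	-0.3747095052	0.8480480962
P1	-0.2869652992	-0.7102640395	0.6427876097
P3	-0.5450074458	-0.6730281451	0.5000000000
P5	-0.7289934749	-0.6337043597	0.2588190451
P7	-0.8085241631	-0.5874271894	-0.0348994967
P9	-0.7332184018	-0.5327143513	-0.4226182617
PO7	-0.5874271894	-0.8085241631	-0.0348994967
PO3	-0.4062467470	-0.8711989604	0.2756373558
O1	-0.3088287496	-0.9504771584	-0.0348994967
Iz	0.0000000000	-0.9063077870	-0.4226182617
Oz	0.0000000000	-0.9993908270	-0.0348994967
POz	0.0000000000	-0.9335804265	0.3583679495
Pz	0.0000000000	-0.7193398003	0.6946583705
CPz	0.0000000000	-0.3907311285	0.9205048535
Fpz	0.0000000000	0.9993908270	-0.0348994967
Fp2	0.3088287496	0.9504771584	-0.0348994967
AF8	0.5874271894	0.8085241631	-0.0348994967
AF4	0.4062467470	0.8711989604	0.2756373558
AFz	0.0000000000	0.9335804265	0.3583679495
Fz	0.0000000000	0.7193398003	0.6946583705
F2	0.2869652992	0.7102640395	0.6427876097
F4	0.5450074458	0.6730281451	0.5000000000
F6	0.7289934749	0.6337043597	0.2588190451
F8	0.8085241631	0.5874271894	-0.0348994967
FT8	0.9504771584	0.3088287496	-0.0348994967
FC6	0.8878877481	0.3408281736	0.3090169944
FC4	0.6763770971	0.3596360819	0.6427876097
FC2	0.3747095052	0.3747095052	0.8480480962
FCz	0.0000000000	0.3907311285	0.9205048535
Cz	0.0000000000	0.0000000000	1.0000000000
C2	0.3907311285	0.0000000000	0.9205048535
C4	0.7193398003	0.0000000000	0.6946583705
C6	0.9335804265	0.0000000000	0.3583679495
T8	0.9993908270	0.0000000000	-0.0348994967
TP8	0.9504771584	-0.3088287496	-0.0348994967
CP6	0.8878877481	-0.3408281736	0.3090169944
CP4	0.6763770971	-0.3596360819	0.6427876097
CP2	0.3747095052	-0.3747095052	0.8480480962
P2	0.2869652992	-0.7102640395	0.6427876097
P4	0.5450074458	-0.6730281451	0.5000000000
P6	0.7289934749	-0.6337043597	0.2588190451
P8	0.8085241631	-0.5874271894	-0.0348994967
P10	0.7332184018	-0.5327143513	-0.4226182617
PO8	0.5874271894	-0.8085241631	-0.0348994967
PO4	0.4062467470	-0.8711989604	0.2756373558
O2	0.3088287496	-0.9504771584	-0.0348994967
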