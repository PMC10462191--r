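label	x	y	z
Fp1	-0.30882874957133	0.95047715836211	-0.03489949670250
AF3	-0.40624674701537	0.87119896040895	0.27563735581700
F7	-0.80852416308088	0.58742718939820	-0.03489949670250
F3	-0.54500744576872	0.67302814507022	0.50000000000000
FC1	-0.37470950522069	0.37470950522068	0.84804809615643
FC5	-0.88788774810577	0.34082817364639	0.30901699437495
T7	-0.99939082701910	-0.00000000000000	-0.03489949670250
C3	-0.71933980033865	-0.00000000000000	0.69465837045900
CP1	-0.37470950522069	-0.37470950522068	0.84804809615643
CP5	-0.88788774810577	-0.34082817364639	0.30901699437495
P7	-0.80852416308088	-0.58742718939820	-0.03489949670250
P3	-0.54500744576872	-0.67302814507022	0.50000000000000
Pz	0.00000000000000	-0.71933980033865	0.69465837045900
PO3	-0.40624674701537	-0.87119896040895	0.27563735581700
O1	-0.30882874957133	-0.95047715836211	-0.03489949670250
Oz	0.00000000000000	-0.99939082701910	-0.03489949670250
O2	0.30882874957133	-0.95047715836211	-0.03489949670250
PO4	0.40624674701537	-0.87119896040895	0.27563735581700
P4	0.54500744576872	-0.67302814507022	0.50000000000000
P8	0.80852416308088	-0.58742718939820	-0.03489949670250
CP6	0.88788774810577	-0.34082817364639	0.30901699437495
CP2	0.37470950522069	-0.37470950522068	0.84804809615643
C4	0.71933980033865	0.00000000000000	0.69465837045900
T8	0.99939082701910	0.00000000000000	-0.03489949670250
FC6	0.88788774810577	0.34082817364639	0.30901699437495
FC2	0.37470950522069	0.37470950522068	0.84804809615643
F4	0.54500744576872	0.67302814507022	0.50000000000000
F8	0.80852416308088	0.58742718939820	-0.03489949670250
AF4	0.40624674701537	0.87119896040895	0.27563735581700
Fp2	0.30882874957133	0.95047715836211	-0.03489949670250
Fz	0.00000000000000	0.71933980033865	0.69465837045900
Cz	0.00000000000000	0.00000000000000	1.00000000000000
M1	-0.72604422139798	-0.37948410426853	-0.57345584239949
M2	0.72471178494026	-0.38019917665372	-0.57466635088591
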