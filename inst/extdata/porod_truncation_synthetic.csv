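# Truncation completeness of the scattering invariants for a
# uniform-density sphere: fraction of int_0^inf q^p I(q) dq accumulated
# below q_max, as a function of x_trunc = q_max * R_equiv with
# R_equiv = Rg / sqrt(3/5). completeness_q2 is for the Porod invariant
# (p = 2, limit 3 pi/2 in reduced units); completeness_q1 for the
# volume-of-correlation denominator (p = 1, limit 9/4).
# SYNTHETIC calibration computed from the closed-form sphere form factor;
# used in place of the empirical PDB-derived coefficients of Fischer et
# al. (2010), J. Appl. Cryst. 43, 101-109, which are not redistributed
# here.
x_trunc,completeness_q2,completeness_q1
2.00,0.351566,0.603723
2.25,0.442062,0.693029
2.50,0.528594,0.769460
2.75,0.605947,0.831296
3.00,0.670317,0.878294
3.25,0.719715,0.911487
3.50,0.754068,0.932871
3.75,0.775025,0.945024
4.00,0.785516,0.950721
4.25,0.789156,0.952583
4.50,0.789622,0.952810
4.75,0.790083,0.953016
5.00,0.792797,0.954177
5.25,0.798908,0.956668
5.50,0.808464,0.960388
5.75,0.820623,0.964913
6.00,0.833989,0.969678
6.25,0.846996,0.974128
6.50,0.858273,0.977835
6.75,0.866907,0.980568
7.00,0.872583,0.982300
7.25,0.875580,0.983183
7.50,0.876641,0.983486
7.75,0.876765,0.983520
8.00,0.876968,0.983574
8.25,0.878067,0.983856
8.50,0.880531,0.984472
8.75,0.884423,0.985416
9.00,0.889435,0.986598
9.25,0.895001,0.987876
9.50,0.900452,0.989094
9.75,0.905178,0.990123
10.00,0.908762,0.990883
10.50,0.912194,0.991589
11.00,0.912558,0.991661
11.50,0.913521,0.991838
12.00,0.917342,0.992518
12.50,0.923278,0.993532
13.00,0.928699,0.994424
13.50,0.931591,0.994882
14.00,0.932170,0.994971
14.50,0.932411,0.995006
15.00,0.934164,0.995254
15.50,0.937618,0.995728
16.00,0.941366,0.996227
16.50,0.943810,0.996543
17.00,0.944556,0.996636
17.50,0.944624,0.996645
18.00,0.945420,0.996738
18.50,0.947490,0.996976
19.00,0.950153,0.997273
19.50,0.952215,0.997498
20.00,0.953065,0.997588
21.00,0.953479,0.997630
22.00,0.956626,0.997936
23.00,0.959253,0.998181
24.00,0.959529,0.998206
25.00,0.961611,0.998383
26.00,0.963947,0.998576
27.00,0.964230,0.998598
28.00,0.965582,0.998701
29.00,0.967625,0.998851
30.00,0.967979,0.998876
31.00,0.968828,0.998934
32.00,0.970584,0.999051
33.00,0.971029,0.999080
34.00,0.971540,0.999112
35.00,0.973018,0.999202
36.00,0.973551,0.999233
37.00,0.973843,0.999250
38.00,0.975059,0.999318
39.00,0.975664,0.999351
40.00,0.975824,0.999359
41.00,0.976800,0.999410
42.00,0.977453,0.999443
43.00,0.977547,0.999447
44.00,0.978308,0.999484
45.00,0.978984,0.999516
46.00,0.979058,0.999519
47.00,0.979631,0.999545
48.00,0.980306,0.999575
49.00,0.980392,0.999578
50.00,0.980805,0.999596
51.00,0.981457,0.999623
52.00,0.981574,0.999628
53.00,0.981859,0.999639
54.00,0.982467,0.999663
55.00,0.982626,0.999669
56.00,0.982812,0.999676
57.00,0.983362,0.999696
58.00,0.983565,0.999704
59.00,0.983679,0.999708
60.00,0.984162,0.999725
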