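# Printed PCA table (displayed PCs, CR >= 1%) of 414 upper-auricle homologous
# ear models from a published forensic CT cohort study; ev in squared mm of
# coordinate variance, cr/ccr in percent, r = Pearson correlation with age.
# total_variance: 14289
pc,ev,cr,ccr,r
1,1437.6,10.1,10.1,-0.01
2,1212.3,8.5,18.5,-0.21
3,1000.8,7.0,25.5,0.27
4,900.3,6.3,31.8,-0.27
5,709.0,5.0,36.8,0.16
6,572.0,4.0,40.8,0.11
7,483.4,3.4,44.2,-0.09
8,449.5,3.1,47.3,0.18
9,390.3,2.7,50.1,-0.13
10,358.2,2.5,52.6,0.04
11,347.4,2.4,55.0,0.00
12,335.7,2.3,57.4,0.16
13,277.1,1.9,59.3,0.07
14,269.6,1.9,61.2,-0.08
15,258.1,1.8,63.0,0.04
16,241.0,1.7,64.7,0.15
17,221.2,1.5,66.2,-0.10
18,205.9,1.4,67.7,-0.03
19,198.8,1.4,69.1,0.09
20,184.0,1.3,70.3,0.06
21,170.4,1.2,71.5,-0.01
22,158.1,1.1,72.6,-0.09
23,153.1,1.1,73.7,-0.06
24,144.2,1.0,74.7,-0.05
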