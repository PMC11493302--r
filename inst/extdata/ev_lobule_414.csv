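# Printed PCA table (displayed PCs, CR >= 1%) of 414 lobule homologous ear
# models from a published forensic CT cohort study; ev in squared mm of
# coordinate variance, cr/ccr in percent, r = Pearson correlation with age.
# total_variance: 2226
pc,ev,cr,ccr,r
1,399,17.9,17.9,0.19
2,314,14.1,32.0,-0.33
3,254,11.4,43.4,-0.29
4,220,9.9,53.3,0.06
5,147,6.6,59.9,0.07
6,110,4.9,64.8,0.04
7,99,4.5,69.3,0.00
8,76,3.4,72.7,-0.03
9,72,3.2,75.9,0.01
10,58,2.6,78.5,-0.03
11,50,2.2,80.8,0.05
12,48,2.2,82.9,-0.01
13,38,1.7,84.7,0.03
14,34,1.5,86.2,0.03
15,32,1.4,87.6,0.06
16,29,1.3,88.9,-0.14
17,25,1.1,90.0,0.08
18,22,1.0,91.0,-0.02
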