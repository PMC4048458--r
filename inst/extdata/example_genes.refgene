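GENE0008	chr1	+	15429	21353
GENE0004	chr1	+	341693	345825
GENE0002	chr1	+	723037	775667
GENE0006	chr1	+	898343	969521
GENE0005	chr1	-	1258297	1272113
GENE0001	chr1	-	1481676	1519817
GENE0007	chr1	+	1692433	1697330
GENE0003	chr1	-	2198019	2204080
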