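ID1: P0001
A1	43.805306680207671
A2	 60.49677525296363
A3	37.176066964839222
A4	54.072829721825087
A5	55.904615128958447
A6	72.305359463691275
A7	61.757007256893388
A8	47.858048019669923
A9	67.423537500741531
A10	45.758072072082008
A11	60.002513878599203
A12	34.897955727113953
B1	77.127355348977687
B2	972.13042581089417
B3	 45.50301580654498
B4	46.326578665047492
B5	33.854659933656635
B6	 51.11084445914053
B7	34.464263238356793
B8	11.044151502847001
B9	 46.88864234711297
B10	63.461919978971153
B11	994.90836962254923
B12	22.185486562450638
C1	64.144280634631045
C2	 973.2025865609013
C3	68.280225108349086
C4	76.853676483939083
C5	145.24117663718116
C6	287.70499540872248
C7	542.00380681026763
C8	777.06346824742116
C9	932.78581289233421
C10	931.49021814896821
C11	1022.6072142918741
C12	36.236889850970492
D1	53.191691674628693
D2	 1017.486368013036
D3	27.645449165623944
D4	87.641670852801553
D5	145.53035375095294
D6	292.64648155002118
D7	480.93277998961787
D8	763.02898949183316
D9	 892.6340739637576
D10	978.53487866458977
D11	1010.8097634390369
D12	36.584417633837333
E1	44.488278109504222
E2	971.80631663949441
E3	114.50878601967041
E4	273.02546760992732
E5	535.98011905436238
E6	745.21843003059632
E7	 927.8684602434945
E8	  950.906694228334
E9	993.73629594782903
E10	1018.4716795653122
E11	1022.3007268204786
E12	41.870598594842008
F1	45.063759951049967
F2	973.18771217052301
F3	124.17784283608513
F4	 280.3771123583366
F5	 533.0294822916328
F6	779.10945084865773
F7	900.56819544080543
F8	973.70838875446725
F9	989.49871418477312
F10	995.58366234237769
F11	1028.6880513242568
F12	80.778803150858522
G1	71.910005172711152
G2	998.52553168647569
G3	15.440244484838551
G4	30.288552928014749
G5	55.747352667230942
G6	25.719022822318529
G7	52.628441904114474
G8	49.031301648539937
G9	85.190803923674324
G10	71.121830121218622
G11	  990.283868886449
G12	39.666259027472059
H1	17.150381610935952
H2	58.944241240074525
H3	50.102355321263801
H4	75.612869925502267
H5	63.757837552688095
H6	79.498434128589324
H7	75.183926802722368
H8	49.348963242629239
H9	43.140745444502556
H10	36.316856976142034
H11	55.358283733982532
H12	34.980012392288053

ID1: P0002
A1	53.429935134573732
A2	64.909946761943075
A3	  24.2898730980435
A4	87.682665918938142
A5	73.530962385362386
A6	72.811730526648319
A7	67.026847800049623
A8	54.820105346416248
A9	60.442406476314545
A10	 86.16404996930639
A11	77.446138669616246
A12	52.190619404582485
B1	38.082172472745448
B2	975.87971412275988
B3	45.671417207749101
B4	45.050722861640509
B5	20.091277663425849
B6	83.334061910271032
B7	18.112087235780173
B8	60.091745357787197
B9	64.299258572980136
B10	46.004739175112284
B11	974.93508256576035
B12	31.353578338675568
C1	43.219667250688147
C2	996.47990817554717
C3	60.970867853247128
C4	82.417223209875573
C5	157.11256815394475
C6	316.47099217241197
C7	550.91633584863007
C8	770.54454347855506
C9	892.74464616935438
C10	967.92861719035704
C11	1022.7814661137056
C12	90.222646541873871
D1	82.632570829699745
D2	993.11856491588037
D3	60.022909721477802
D4	138.29309235549135
D5	144.10426303929719
D6	279.15829984724633
D7	507.70747974625067
D8	766.58858686627627
D9	921.32545371064612
D10	951.91988223097269
D11	1051.9925657392655
D12	  28.7095400981237
E1	  58.2255654945412
E2	989.25213420526416
E3	162.84412297472053
E4	298.82487656729023
E5	 501.6038081084634
E6	770.13838968245034
E7	899.22815576743142
E8	980.99678372687367
E9	982.76570810392161
E10	1027.1592877560342
E11	988.87688570617843
E12	50.618005097902348
F1	37.127287003151416
F2	989.18297426338063
F3	 140.6495636960673
F4	312.62792256112334
F5	561.90637258364336
F6	787.34668261995716
F7	909.82165023320829
F8	956.03660682010786
F9	991.61582401844282
F10	1007.8389565584413
F11	991.20263994446225
F12	56.679140539274037
G1	39.384588287567716
G2	1000.0930154747721
G3	72.353503778537927
G4	88.103786579608936
G5	20.235963228862971
G6	 47.11727286803837
G7	47.329793654605602
G8	45.849990407471509
G9	50.891025508074392
G10	16.591343446085091
G11	966.92927031951126
G12	44.920184440364615
H1	66.220996705024987
H2	44.107490018046363
H3	 15.45766272826382
H4	49.864262967885182
H5	36.628681482789084
H6	52.791876189016833
H7	40.589263760044602
H8	24.729324952475569
H9	40.128888340243797
H10	28.307597961165001
H11	77.279161585792167
H12	49.142357193541088
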