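area_id,practice_id,weight
A0008,P001,0.19676948621055088
A0012,P001,0.7938545706305689
A0015,P001,0.04414658047763339
A0019,P001,0.7146121786638896
A0001,P002,0.19802240465624737
A0003,P002,0.283405854952446
A0005,P002,0.3433220879510112
A0009,P002,1
A0018,P002,0.15693425257435584
A0020,P002,0.29700702020295555
A0008,P003,0.24559799792078219
A0018,P003,0.3400488111798349
A0020,P003,0.33675521465927566
A0012,P004,0.20614542936943114
A0001,P005,0.652325847617897
A0006,P005,1
A0017,P005,1
A0002,P006,0.4718984395422791
A0003,P006,0.39179535982861324
A0005,P006,0.3677869614790991
A0010,P006,0.6298487853489598
A0016,P006,0.3266235005484908
A0018,P006,0.18402658946342276
A0020,P006,0.14403028369533788
A0004,P007,1
A0005,P008,0.08949364144743327
A0008,P008,0.19547560507579498
A0010,P008,0.11118403906444023
A0015,P008,0.3717195179873357
A0020,P008,0.22220748144243088
A0011,P009,0.2737799517687918
A0015,P009,0.42913694636492616
A0018,P009,0.3189903467823865
A0002,P010,0.37521698476001303
A0003,P010,0.32479878521894073
A0007,P010,1
A0008,P010,0.3621569107928718
A0013,P010,1
A0014,P010,1
A0001,P011,0.14965174772585568
A0011,P011,0.7262200482312082
A0016,P011,0.4445579856725073
A0019,P011,0.2853878213361103
A0002,P012,0.15288457569770786
A0005,P012,0.19939730912245637
A0010,P012,0.2589671755865999
A0015,P012,0.15499695517010476
A0016,P012,0.22881851377900195
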