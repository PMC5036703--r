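practice_id,z_1,z_2,z_3,z_4,n_1,n_2,n_3,n_4,w_1,w_2,w_3,w_4,v_1,v_2,v_3,v_4,admissions,deprivation,morbidity,gp_rate,list_size,expected
P001,172,263,327,66,196,388,506,84,63,73,141,106,97,121,162,137,96,0.9684892913019935,0.2354345131938223,-0.7104805190302373,-1.5770619962101327,49.382253607614366
P002,63,433,374,352,71,569,576,403,20,37,46,14,107,174,191,88,113,1.9653678081681896,1.738932091034521,-0.7347336306218151,1.1194230175154314,68.10039914031317
P003,183,121,71,566,192,135,88,586,38,34,34,51,144,138,103,171,48,0.8863225267454674,-0.6314263481670702,-0.08142792206971314,-0.46448399545768865,42.105311636475285
P004,204,373,340,252,210,442,453,263,4,2,0,3,144,87,60,138,36,0.03054026022709051,-1.0461966632286672,-0.8677295003234506,-1.0873838636491486,57.54252379490328
P005,201,288,303,154,208,342,349,159,31,85,76,142,75,132,91,191,49,0.9495574245348903,0.8783439108965615,-1.4087477669204944,-0.4034653369543238,44.50291679459625
P006,501,160,288,176,559,219,444,196,12,2,5,11,134,68,159,195,33,-0.5767300110686207,-0.6282365164923918,1.7989756562558723,1.8174117166409753,59.645686214307645
P007,545,456,117,396,578,530,139,413,24,54,40,39,99,195,90,110,79,0.721523351166167,1.173595238990392,-1.9281681744594832,-0.043702535572579373,69.82499232422475
P008,328,441,250,464,348,500,316,498,4,2,4,6,170,122,93,117,54,0.6190989020629973,1.4838662465566088,1.0124635430623672,0.8314096532135461,69.90911882100092
P009,125,107,298,306,138,147,415,327,19,5,25,11,152,63,186,71,34,0.021005820733917727,-0.6000316941657627,1.4739472055185412,0.18782542839630728,43.19895609456555
P010,305,232,36,344,369,329,79,427,23,20,23,33,124,118,80,143,68,0.27485017564488756,0.8835703590060638,-0.28011105228074146,0.27029926914308716,50.644151059256984
P011,377,455,190,534,396,538,250,558,8,5,2,7,157,134,61,196,36,-1.4176366940914,-0.23874575256079533,-0.941076042145318,-0.4226147134266315,73.2741786920479
P012,113,312,175,468,133,413,262,544,24,19,34,28,111,154,116,149,39,-1.781310755171869,-1.1102761347551677,-0.41932762808716056,-0.35797860455967384,56.86951182069389
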