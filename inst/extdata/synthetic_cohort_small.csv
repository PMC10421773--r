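participant_id,sex,age_years,tooth_fdi,hard_ml,hsst_ml,lsst_ml
P0001,F,           21.75,46,          0.9788,         0.03143,          0.0161
P0001,F,           21.75,47,           1.081,         0.03263,         0.01458
P0002,F,           19.41,46,          0.9581,         0.03798,         0.01945
P0002,F,           19.41,47,           1.011,         0.04333,         0.01936
P0003,F,           15.24,46,           1.244,         0.07032,         0.03602
P0003,F,           15.24,47,           1.323,          0.1129,         0.05046
P0004,F,           21.42,46,           1.322,         0.05451,         0.02792
P0004,F,           21.42,47,           1.095,         0.04339,         0.01939
P0005,F,           14.12,46,           1.192,         0.05991,         0.03068
P0005,F,           14.12,47,           1.011,         0.08265,         0.03693
P0006,F,           23.52,46,          0.9767,         0.03492,         0.01789
P0006,F,           23.52,47,          0.6247,         0.01996,        0.008917
P0007,F,           20.12,46,           1.198,         0.03976,         0.02037
P0007,F,           20.12,47,          0.9861,         0.03931,         0.01756
P0008,F,           22.87,46,            1.29,         0.03948,         0.02022
P0008,F,           22.87,47,            1.41,         0.04518,         0.02019
P0009,F,           14.37,46,           1.014,         0.04778,         0.02447
P0009,F,           14.37,47,          0.9535,         0.06273,         0.02803
P0010,F,           23.03,46,          0.6379,         0.01988,         0.01018
P0010,F,           23.03,47,          0.9923,         0.03251,         0.01453
P0011,F,            23.5,46,           1.162,         0.03655,         0.01872
P0011,F,            23.5,47,           0.811,         0.02321,         0.01037
P0012,F,           19.49,46,           1.398,         0.05824,         0.02983
P0012,F,           19.49,47,           0.921,         0.04223,         0.01887
P0013,M,           19.57,46,             1.2,         0.06076,         0.02933
P0013,M,           19.57,47,          0.9796,         0.05997,         0.02399
P0014,M,           20.65,46,           1.154,          0.0555,         0.02679
P0014,M,           20.65,47,          0.7165,          0.0394,         0.01576
P0015,M,           19.55,46,           1.024,         0.04372,         0.02111
P0015,M,           19.55,47,           1.127,           0.053,          0.0212
P0016,M,           19.32,46,           1.453,         0.05717,          0.0276
P0016,M,           19.32,47,            1.08,         0.05671,         0.02268
P0017,M,           22.16,46,           1.461,         0.04342,         0.02096
P0017,M,           22.16,47,           1.592,         0.07538,         0.03015
P0018,M,           23.24,46,           1.808,         0.06836,           0.033
P0018,M,           23.24,47,          0.8212,         0.03709,         0.01483
P0019,M,           21.27,46,           1.662,         0.07749,         0.03741
P0019,M,           21.27,47,           1.362,         0.07454,         0.02982
P0020,M,           18.28,46,           1.196,         0.07665,         0.03701
P0020,M,           18.28,47,           1.066,         0.08444,         0.03378
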