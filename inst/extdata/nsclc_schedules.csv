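case_id,period,day,drug
1,between_cts,1,gemcitabine
1,between_cts,8,gemcitabine
1,between_cts,22,gemcitabine
1,between_cts,29,gemcitabine
1,between_cts,1,cisplatin
1,between_cts,22,cisplatin
2,between_cts,1,gemcitabine
2,between_cts,8,gemcitabine
2,between_cts,22,gemcitabine
2,between_cts,29,gemcitabine
2,between_cts,1,cisplatin
2,between_cts,22,cisplatin
2,ct2_to_surgery,43,gemcitabine
2,ct2_to_surgery,50,gemcitabine
2,ct2_to_surgery,43,cisplatin
3,between_cts,1,gemcitabine
3,between_cts,8,gemcitabine
3,between_cts,22,gemcitabine
3,between_cts,30,gemcitabine
3,between_cts,1,cisplatin
3,between_cts,22,cisplatin
4,between_cts,1,docetaxel
4,between_cts,22,docetaxel
4,between_cts,1,cisplatin
4,between_cts,22,cisplatin
4,ct2_to_surgery,44,docetaxel
4,ct2_to_surgery,44,cisplatin
5,between_cts,1,vinorelbine
5,between_cts,8,vinorelbine
5,between_cts,22,vinorelbine
5,between_cts,29,vinorelbine
5,between_cts,1,cisplatin
5,between_cts,22,cisplatin
6,between_cts,1,vinorelbine
6,between_cts,8,vinorelbine
6,between_cts,22,vinorelbine
6,between_cts,29,vinorelbine
6,between_cts,43,vinorelbine
6,between_cts,1,cisplatin
6,between_cts,22,cisplatin
6,between_cts,43,cisplatin
6,ct2_to_surgery,50,vinorelbine
7,between_cts,1,vinorelbine
7,between_cts,22,vinorelbine
7,between_cts,29,vinorelbine
7,between_cts,1,cisplatin
7,between_cts,22,cisplatin
8,between_cts,1,vinorelbine
8,between_cts,8,vinorelbine
8,between_cts,22,vinorelbine
8,between_cts,29,vinorelbine
8,between_cts,1,cisplatin
8,between_cts,22,cisplatin
9,between_cts,1,vinorelbine
9,between_cts,8,vinorelbine
9,between_cts,29,vinorelbine
9,between_cts,36,vinorelbine
9,between_cts,1,cisplatin
9,between_cts,29,cisplatin
10,between_cts,1,vinorelbine
10,between_cts,8,vinorelbine
10,between_cts,22,vinorelbine
10,between_cts,29,vinorelbine
10,between_cts,1,cisplatin
10,between_cts,22,cisplatin
11,between_cts,1,vinorelbine
11,between_cts,8,vinorelbine
11,between_cts,26,vinorelbine
11,between_cts,33,vinorelbine
11,between_cts,1,cisplatin
11,between_cts,26,cisplatin
12,between_cts,1,vinorelbine
12,between_cts,8,vinorelbine
12,between_cts,22,vinorelbine
12,between_cts,29,vinorelbine
12,between_cts,1,cisplatin
12,between_cts,22,cisplatin
13,between_cts,1,vinorelbine
13,between_cts,8,vinorelbine
13,between_cts,36,vinorelbine
13,between_cts,43,vinorelbine
13,between_cts,64,vinorelbine
13,between_cts,71,vinorelbine
13,between_cts,1,cisplatin
13,between_cts,36,cisplatin
13,between_cts,64,cisplatin
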