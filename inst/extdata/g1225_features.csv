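feature_id,rt_min,mz_observed,formula,adduct
1,2.81,527.2838,C28H38N4O6,[M+H]+
2,6.37,518.2643,C26H29NO5,[M+2ACN+H]+
3,14.50,387.1814,C22H26O6,[M+H]+
4,15.22,393.2877,C17H30N2O3,[M+2ACN+H]+
5,15.69,437.1947,C26H28O6,[M+H]+
6,16.30,415.2129,C24H30O6,[M+H]+
7,20.00,692.4602,C37H55NO6,[M+2ACN+H]+
8,20.12,648.4338,C32H54N4O7,[M+ACN+H]+
9,21.07,546.4901,C35H63NO3,[M+H]+
10,21.79,991.5576,C42H75N7O17,[M+ACN+H]+
11,22.70,412.2968,C21H31NO2,[M+2ACN+H]+
12,22.85,654.3348,C27H37N7O7,[M+2ACN+H]+
13,22.93,669.3346,C31H42N2O7S,[M+2ACN+H]+
14,23.02,663.4566,C42H63O4P,[M+H]+
15,23.34,685.4385,C34H60N4O10,[M+H]+
16,23.44,376.3202,C22H38O2,[M+ACN+H]+
17,25.29,612.1849,C32H26O10,[M+ACN+H]+
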