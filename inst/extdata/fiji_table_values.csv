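t,per_person_000
40,140.4
35,117.7
30,114.9
25,100.2
20,83.9
15,65.9
10,46.1
5,24.2
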