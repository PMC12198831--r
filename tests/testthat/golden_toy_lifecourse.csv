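"person_id","discounted_cost","discounted_qaly","discounted_ly","crc_death_probability","stage_at_diagnosis"
1,0,7.98225175012431,9.97781468765538,0,"none"
2,1614.28568704856,2.45142847337481,3.57142843524278,0.714285687048557,"II"
3,0,7.88175293646853,9.85219117058566,0,"none"
4,1107.35620265658,3.81348032612517,5.11802850898476,0.540356202656584,"I"
5,0,6.91931862586161,8.64914828232701,0,"none"
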