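measure,sex,age_y,L,M,S
bmi,M,5,-0.5,15.6905302216095,0.115
bmi,F,5,-0.5,15.9405302216095,0.119
bmi,M,6,-0.5,15.8605982077849,0.115
bmi,F,6,-0.5,16.1105982077849,0.119
bmi,M,7,-0.5,16.0821016229637,0.115
bmi,F,7,-0.5,16.3321016229637,0.119
bmi,M,8,-0.5,16.3650374357038,0.115
bmi,F,8,-0.5,16.6150374357038,0.119
bmi,M,9,-0.5,16.7175951655832,0.115
bmi,F,9,-0.5,16.9675951655832,0.119
bmi,M,10,-0.5,17.143584584828,0.115
bmi,F,10,-0.5,17.393584584828,0.119
bmi,M,11,-0.5,17.6395589075311,0.115
bmi,F,11,-0.5,17.8895589075311,0.119
bmi,M,12,-0.5,18.1926812722129,0.115
bmi,F,12,-0.5,18.4426812722129,0.119
bmi,M,13,-0.5,18.7806865435935,0.115
bmi,F,13,-0.5,19.0306865435935,0.119
bmi,M,14,-0.5,19.3747873123602,0.115
bmi,F,14,-0.5,19.6247873123602,0.119
bmi,M,15,-0.5,19.9449972487418,0.115
bmi,F,15,-0.5,20.1949972487418,0.119
bmi,M,16,-0.5,20.4659284705547,0.115
bmi,F,16,-0.5,20.7159284705547,0.119
bmi,M,17,-0.5,20.9208198427584,0.115
bmi,F,17,-0.5,21.1708198427584,0.119
bmi,M,18,-0.5,21.3026368574239,0.115
bmi,F,18,-0.5,21.5526368574239,0.119
bmi,M,19,-0.5,21.6126195803842,0.115
bmi,F,19,-0.5,21.8626195803842,0.119
bmi,M,20,-0.5,21.8575480545347,0.115
bmi,F,20,-0.5,22.1075480545347,0.119
bmi,M,21,-0.5,22.0469596555002,0.115
bmi,F,21,-0.5,22.2969596555002,0.119
bmi,M,22,-0.5,22.1910177532842,0.115
bmi,F,22,-0.5,22.4410177532842,0.119
fmi,M,5,0,3.13810604432189,0.38
fmi,F,5,0,3.98513255540237,0.4
fmi,M,6,0,3.17211964155697,0.38
fmi,F,6,0,4.02764955194621,0.4
fmi,M,7,0,3.21642032459273,0.38
fmi,F,7,0,4.08302540574092,0.4
fmi,M,8,0,3.27300748714077,0.38
fmi,F,8,0,4.15375935892596,0.4
fmi,M,9,0,3.34351903311664,0.38
fmi,F,9,0,4.2418987913958,0.4
fmi,M,10,0,3.42871691696561,0.38
fmi,F,10,0,4.34839614620701,0.4
fmi,M,11,0,3.52791178150622,0.38
fmi,F,11,0,4.47238972688277,0.4
fmi,M,12,0,3.63853625444258,0.38
fmi,F,12,0,4.61067031805323,0.4
fmi,M,13,0,3.75613730871871,0.38
fmi,F,13,0,4.75767163589839,0.4
fmi,M,14,0,3.87495746247205,0.38
fmi,F,14,0,4.90619682809006,0.4
fmi,M,15,0,3.98899944974836,0.38
fmi,F,15,0,5.04874931218545,0.4
fmi,M,16,0,4.09318569411095,0.38
fmi,F,16,0,5.17898211763868,0.4
fmi,M,17,0,4.18416396855168,0.38
fmi,F,17,0,5.29270496068959,0.4
fmi,M,18,0,4.26052737148477,0.38
fmi,F,18,0,5.38815921435597,0.4
fmi,M,19,0,4.32252391607685,0.38
fmi,F,19,0,5.46565489509606,0.4
fmi,M,20,0,4.37150961090694,0.38
fmi,F,20,0,5.52688701363368,0.4
fmi,M,21,0,4.40939193110004,0.38
fmi,F,21,0,5.57423991387505,0.4
fmi,M,22,0,4.43820355065684,0.38
fmi,F,22,0,5.61025443832105,0.4
lmi,M,5,0,12.5524241772876,0.11
lmi,F,5,0,11.9553976662071,0.11
lmi,M,6,0,12.6884785662279,0.11
lmi,F,6,0,12.0829486558386,0.11
lmi,M,7,0,12.8656812983709,0.11
lmi,F,7,0,12.2490762172228,0.11
lmi,M,8,0,13.0920299485631,0.11
lmi,F,8,0,12.4612780767779,0.11
lmi,M,9,0,13.3740761324666,0.11
lmi,F,9,0,12.7256963741874,0.11
lmi,M,10,0,13.7148676678624,0.11
lmi,F,10,0,13.045188438621,0.11
lmi,M,11,0,14.1116471260249,0.11
lmi,F,11,0,13.4171691806483,0.11
lmi,M,12,0,14.5541450177703,0.11
lmi,F,12,0,13.8320109541597,0.11
lmi,M,13,0,15.0245492348748,0.11
lmi,F,13,0,14.2730149076952,0.11
lmi,M,14,0,15.4998298498882,0.11
lmi,F,14,0,14.7185904842702,0.11
lmi,M,15,0,15.9559977989934,0.11
lmi,F,15,0,15.1462479365563,0.11
lmi,M,16,0,16.3727427764438,0.11
lmi,F,16,0,15.5369463529161,0.11
lmi,M,17,0,16.7366558742067,0.11
lmi,F,17,0,15.8781148820688,0.11
lmi,M,18,0,17.0421094859391,0.11
lmi,F,18,0,16.1644776430679,0.11
lmi,M,19,0,17.2900956643074,0.11
lmi,F,19,0,16.3969646852882,0.11
lmi,M,20,0,17.4860384436278,0.11
lmi,F,20,0,16.580661040901,0.11
lmi,M,21,0,17.6375677244001,0.11
lmi,F,21,0,16.7227197416251,0.11
lmi,M,22,0,17.7528142026274,0.11
lmi,F,22,0,16.8307633149631,0.11
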