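# T: 298
# referenced: yes
#! FIELDS z w
0 0
0.010050251256281407 0
0.020100502512562814 0
0.03015075376884422 0
0.040201005025125629 0
0.050251256281407038 0
0.06030150753768844 0
0.070351758793969849 0
0.080402010050251257 0
0.090452261306532666 0
0.10050251256281408 0
0.11055276381909548 0
0.12060301507537688 0
0.1306532663316583 0
0.1407035175879397 0
0.15075376884422112 0
0.16080402010050251 0
0.17085427135678391 0
0.18090452261306533 0
0.19095477386934673 0
0.20100502512562815 0
0.21105527638190955 0
0.22110552763819097 0
0.23115577889447236 0
0.24120603015075376 0
0.25125628140703515 0
0.2613065326633166 0
0.271356783919598 0
0.28140703517587939 0
0.29145728643216079 0
0.30150753768844224 0
0.31155778894472363 0
0.32160804020100503 0
0.33165829145728642 0
0.34170854271356782 0
0.35175879396984927 0
0.36180904522613067 0
0.37185929648241206 0
0.38190954773869346 0
0.39195979899497491 0
0.4020100502512563 0
0.4120603015075377 0
0.42211055276381909 0
0.43216080402010049 0
0.44221105527638194 0
0.45226130653266333 0
0.46231155778894473 0
0.47236180904522612 0
0.48241206030150752 0
0.49246231155778897 0
0.50251256281407031 0
0.51256281407035176 0
0.52261306532663321 0
0.53266331658291455 0
0.542713567839196 0
0.55276381909547745 0
0.56281407035175879 0
0.57286432160804024 0
0.58291457286432158 0
0.59296482412060303 0
0.60301507537688448 0
0.61306532663316582 0
0.62311557788944727 0
0.63316582914572861 0
0.64321608040201006 0
0.65326633165829151 0
0.66331658291457285 0
0.6733668341708543 0
0.68341708542713564 0
0.69346733668341709 0
0.70351758793969854 0
0.71356783919597988 0
0.72361809045226133 0
0.73366834170854267 0
0.74371859296482412 0
0.75376884422110557 0
0.76381909547738691 0
0.77386934673366836 0
0.78391959798994981 0
0.79396984924623115 0
0.8040201005025126 0
0.81407035175879394 0
0.82412060301507539 0
0.83417085427135684 0
0.84422110552763818 0
0.85427135678391963 0
0.86432160804020097 0
0.87437185929648242 0
0.88442211055276387 0
0.89447236180904521 0
0.90452261306532666 0
0.914572864321608 0
0.92462311557788945 0
0.9346733668341709 0
0.94472361809045224 0
0.95477386934673369 0
0.96482412060301503 0
0.97487437185929648 0
0.98492462311557794 0
0.99497487437185927 0
1.0050251256281406 0
1.0150753768844221 0
1.0251256281407035 0
1.035175879396985 0
1.0452261306532664 0
1.0552763819095476 0
1.0653266331658291 0
1.0753768844221105 0
1.085427135678392 0
1.0954773869346734 0
1.1055276381909549 0
1.1155778894472361 0
1.1256281407035176 0
1.135678391959799 0
1.1457286432160805 0
1.1557788944723619 0
1.1658291457286432 0
1.1758793969849246 0
1.1859296482412061 0
1.1959798994974875 0
1.206030150753769 0
1.2160804020100502 0
1.2261306532663316 0
1.2361809045226131 0
1.2462311557788945 0
1.256281407035176 0
1.2663316582914572 0
1.2763819095477387 0
1.2864321608040201 0
1.2964824120603016 0
1.306532663316583 0
1.3165829145728642 0
1.3266331658291457 0
1.3366834170854272 0
1.3467336683417086 0
1.3567839195979901 0
1.3668341708542713 0
1.3768844221105527 0
1.3869346733668342 0
1.3969849246231156 0
1.4070351758793971 0
1.4170854271356783 0
1.4271356783919598 0
1.4371859296482412 0
1.4472361809045227 0
1.4572864321608041 0
1.4673366834170853 0
1.4773869346733668 0
1.4874371859296482 0
1.4974874371859297 0
1.5075376884422111 0
1.5175879396984926 0
1.5276381909547738 0
1.5376884422110553 0
1.5477386934673367 0
1.5577889447236182 0
1.5678391959798996 0
1.5778894472361809 0
1.5879396984924623 0
1.5979899497487438 0
1.6080402010050252 0
1.6180904522613067 0
1.6281407035175879 0
1.6381909547738693 0
1.6482412060301508 0
1.6582914572864322 0
1.6683417085427137 0
1.6783919597989949 0
1.6884422110552764 0
1.6984924623115578 0
1.7085427135678393 0
1.7185929648241207 0
1.7286432160804019 0
1.7386934673366834 0
1.7487437185929648 0
1.7587939698492463 0
1.7688442211055277 0
1.778894472361809 0
1.7889447236180904 0
1.7989949748743719 0
1.8090452261306533 0
1.8190954773869348 0
1.829145728643216 0
1.8391959798994975 0
1.8492462311557789 0
1.8592964824120604 0
1.8693467336683418 0
1.879396984924623 0
1.8894472361809045 0
1.8994974874371859 0
1.9095477386934674 0
1.9195979899497488 0
1.9296482412060301 0
1.9396984924623115 0
1.949748743718593 0
1.9597989949748744 0
1.9698492462311559 0
1.9798994974874373 0
1.9899497487437185 0
2 0
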