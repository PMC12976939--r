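case_id,n_patches,median,q1,q3,histology,microbiology,mdt
case01,339,167,45,263,infected,growth,infected
case02,165,27,1,18,infected,growth,infected
case03,1579,20,3,14,infected,growth,infected
case04,3625,11,2,9,infected,growth,infected
case05,3376,9,2,8,infected,growth,infected
case06,96,7,1,8,infected,no_growth,infected
case07,832,7,2,8,uncertain,growth,infected
case08,34,6,3,8,not_infected,growth,infected
case09,431,5,1,6,not_infected,no_growth,not_infected
case10,504,5,2,6,infected,growth,infected
case11,385,3,1,3,not_infected,no_growth,not_infected
case12,505,3,1,3,not_infected,no_growth,not_infected
case13,397,3,1,3,infected,no_growth,infected
case14,239,3,1,4,not_infected,no_growth,not_infected
case15,321,3,1,3,uncertain,no_growth,not_infected
case16,673,2,1,2,infected,growth,infected
case17,46,2,1,2,not_infected,no_growth,not_infected
case18,218,2,1,2,not_infected,no_growth,not_infected
case19,21,1,1,1,not_infected,no_growth,not_infected
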