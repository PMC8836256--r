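mirna_id	gene
syn-miR-1	G017
syn-miR-1	G005
syn-miR-1	G001
syn-miR-1	G025
syn-miR-1	G010
syn-miR-1	G004
syn-miR-1	G176
syn-miR-1	G152
syn-miR-1	G079
syn-miR-1	G158
syn-miR-1	G077
syn-miR-2	G024
syn-miR-2	G007
syn-miR-2	G004
syn-miR-2	G025
syn-miR-2	G005
syn-miR-2	G014
syn-miR-2	G050
syn-miR-2	G184
syn-miR-2	G144
syn-miR-2	G141
syn-miR-2	G161
syn-miR-3	G009
syn-miR-3	G025
syn-miR-3	G027
syn-miR-3	G004
syn-miR-3	G005
syn-miR-3	G013
syn-miR-3	G035
syn-miR-3	G192
syn-miR-3	G122
syn-miR-3	G134
syn-miR-3	G033
syn-miR-4	G026
syn-miR-4	G001
syn-miR-4	G010
syn-miR-4	G024
syn-miR-4	G011
syn-miR-4	G015
syn-miR-4	G180
syn-miR-4	G088
syn-miR-4	G166
syn-miR-4	G066
syn-miR-4	G098
syn-miR-5	G022
syn-miR-5	G018
syn-miR-5	G013
syn-miR-5	G005
syn-miR-5	G004
syn-miR-5	G002
syn-miR-5	G129
syn-miR-5	G184
syn-miR-5	G144
syn-miR-5	G036
syn-miR-5	G164
syn-miR-6	G002
syn-miR-6	G020
syn-miR-6	G003
syn-miR-6	G022
syn-miR-6	G021
syn-miR-6	G030
syn-miR-6	G132
syn-miR-6	G168
syn-miR-6	G070
syn-miR-6	G035
syn-miR-6	G063
syn-miR-7	G017
syn-miR-7	G007
syn-miR-7	G004
syn-miR-7	G013
syn-miR-7	G010
syn-miR-7	G009
syn-miR-7	G187
syn-miR-7	G106
syn-miR-7	G039
syn-miR-7	G065
syn-miR-7	G046
syn-miR-8	G005
syn-miR-8	G028
syn-miR-8	G024
syn-miR-8	G014
syn-miR-8	G030
syn-miR-8	G022
syn-miR-8	G160
syn-miR-8	G112
syn-miR-8	G182
syn-miR-8	G143
syn-miR-8	G176
syn-miR-9	G005
syn-miR-9	G014
syn-miR-9	G008
syn-miR-9	G023
syn-miR-9	G028
syn-miR-9	G021
syn-miR-9	G087
syn-miR-9	G130
syn-miR-9	G072
syn-miR-9	G176
syn-miR-9	G121
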