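"sex","age","L","M","S"
"male",2,-1.46,15.38,0.086
"male",2.5,-1.45,15.28125,0.0875
"male",3,-1.44,15.205,0.089
"male",3.5,-1.43,15.15125,0.0905
"male",4,-1.42,15.12,0.092
"male",4.5,-1.41,15.11125,0.0935
"male",5,-1.4,15.125,0.095
"male",5.5,-1.39,15.16125,0.0965
"male",6,-1.38,15.22,0.098
"male",6.5,-1.37,15.30125,0.0995
"male",7,-1.36,15.405,0.101
"male",7.5,-1.35,15.53125,0.1025
"male",8,-1.34,15.68,0.104
"male",8.5,-1.33,15.85125,0.1055
"male",9,-1.32,16.045,0.107
"male",9.5,-1.31,16.26125,0.1085
"male",10,-1.3,16.5,0.11
"male",10.5,-1.29,16.76125,0.1115
"male",11,-1.28,17.045,0.113
"male",11.5,-1.27,17.35125,0.1145
"male",12,-1.26,17.68,0.116
"male",12.5,-1.25,18.03125,0.1175
"male",13,-1.24,18.405,0.119
"male",13.5,-1.23,18.80125,0.1205
"male",14,-1.22,19.22,0.122
"male",14.5,-1.21,19.66125,0.1235
"male",15,-1.2,20.125,0.125
"male",15.5,-1.19,20.61125,0.1265
"male",16,-1.18,21.12,0.128
"male",16.5,-1.17,21.65125,0.1295
"male",17,-1.16,22.205,0.131
"male",17.5,-1.15,22.78125,0.1325
"male",18,-1.14,23.38,0.134
"female",2,-1.46,15.18,0.091
"female",2.5,-1.45,15.08125,0.0925
"female",3,-1.44,15.005,0.094
"female",3.5,-1.43,14.95125,0.0955
"female",4,-1.42,14.92,0.097
"female",4.5,-1.41,14.91125,0.0985
"female",5,-1.4,14.925,0.1
"female",5.5,-1.39,14.96125,0.1015
"female",6,-1.38,15.02,0.103
"female",6.5,-1.37,15.10125,0.1045
"female",7,-1.36,15.205,0.106
"female",7.5,-1.35,15.33125,0.1075
"female",8,-1.34,15.48,0.109
"female",8.5,-1.33,15.65125,0.1105
"female",9,-1.32,15.845,0.112
"female",9.5,-1.31,16.06125,0.1135
"female",10,-1.3,16.3,0.115
"female",10.5,-1.29,16.56125,0.1165
"female",11,-1.28,16.845,0.118
"female",11.5,-1.27,17.15125,0.1195
"female",12,-1.26,17.48,0.121
"female",12.5,-1.25,17.83125,0.1225
"female",13,-1.24,18.205,0.124
"female",13.5,-1.23,18.60125,0.1255
"female",14,-1.22,19.02,0.127
"female",14.5,-1.21,19.46125,0.1285
"female",15,-1.2,19.925,0.13
"female",15.5,-1.19,20.41125,0.1315
"female",16,-1.18,20.92,0.133
"female",16.5,-1.17,21.45125,0.1345
"female",17,-1.16,22.005,0.136
"female",17.5,-1.15,22.58125,0.1375
"female",18,-1.14,23.18,0.139
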