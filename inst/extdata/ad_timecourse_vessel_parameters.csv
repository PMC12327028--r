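# Reference longitudinal vessel-parameter series: murine atopic-dermatitis OCTA time course,
# days 0-14 (normal: day 0; modeling: days 2-6; treatment: days 8-14).
# value: measured parameter (VA/VS voxel or pixel counts; VAD/VSD dimensionless densities).
# printed_rate: published average rate of change for the series (3 decimals).
# Label caveat: in the 2D block the VSD row holds skeleton counts and the VS row holds
# densities; labels preserved as printed. The 2D VAD printed_rate 0.169 recomputes to 0.168.
"dims","parameter","day","value","printed_rate"
"3D","VA",0,278504,0.289
"3D","VA",2,234977,0.289
"3D","VA",4,317641,0.289
"3D","VA",6,434710,0.289
"3D","VA",8,495952,0.289
"3D","VA",10,605974,0.289
"3D","VA",12,276343,0.289
"3D","VA",14,210057,0.289
"3D","VS",0,7968,0.273
"3D","VS",2,10078,0.273
"3D","VS",4,10451,0.273
"3D","VS",6,12230,0.273
"3D","VS",8,18075,0.273
"3D","VS",10,14495,0.273
"3D","VS",12,9430,0.273
"3D","VS",14,5560,0.273
"3D","VAD",0,0.0754,0.229
"3D","VAD",2,0.079,0.229
"3D","VAD",4,0.0844,0.229
"3D","VAD",6,0.1007,0.229
"3D","VAD",8,0.1569,0.229
"3D","VAD",10,0.1398,0.229
"3D","VAD",12,0.0677,0.229
"3D","VAD",14,0.0604,0.229
"3D","VSD",0,0.00216,0.186
"3D","VSD",2,0.00277,0.186
"3D","VSD",4,0.00282,0.186
"3D","VSD",6,0.00283,0.186
"3D","VSD",8,0.00366,0.186
"3D","VSD",10,0.00334,0.186
"3D","VSD",12,0.00231,0.186
"3D","VSD",14,0.0016,0.186
"2D","VA",0,35553,0.211
"2D","VA",2,38541,0.211
"2D","VA",4,41029,0.211
"2D","VA",6,47283,0.211
"2D","VA",8,65793,0.211
"2D","VA",10,52166,0.211
"2D","VA",12,43737,0.211
"2D","VA",14,25485,0.211
"2D","VSD",0,6720,0.168
"2D","VSD",2,6721,0.168
"2D","VSD",4,8066,0.168
"2D","VSD",6,8499,0.168
"2D","VSD",8,10134,0.168
"2D","VSD",10,8459,0.168
"2D","VSD",12,7020,0.168
"2D","VSD",14,4248,0.168
"2D","VS",0,0.2743,0.211
"2D","VS",2,0.2974,0.211
"2D","VS",4,0.3166,0.211
"2D","VS",6,0.3648,0.211
"2D","VS",8,0.5077,0.211
"2D","VS",10,0.4025,0.211
"2D","VS",12,0.3375,0.211
"2D","VS",14,0.1966,0.211
"2D","VAD",0,0.05185,0.169
"2D","VAD",2,0.05186,0.169
"2D","VAD",4,0.06224,0.169
"2D","VAD",6,0.06558,0.169
"2D","VAD",8,0.07819,0.169
"2D","VAD",10,0.06527,0.169
"2D","VAD",12,0.05417,0.169
"2D","VAD",14,0.03278,0.169
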