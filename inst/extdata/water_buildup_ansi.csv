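energy_MeV,depth_mfp,B_ansi,B_gp,percent_error
0.15,1,3.91,3.84,1.84
0.15,2,9.36,9.37,0.07
0.15,3,18.6,18.3,1.62
0.15,4,32.5,31.6,2.76
0.15,5,52.0,50.39,3.09
0.15,6,77.9,75.87,2.6
0.15,7,111.0,109.33,1.5
0.15,8,153.0,152.1,0.59
0.15,10,268.0,270.97,1.11
0.15,15,805.0,825.45,2.54
0.15,20,1890.0,1897.57,0.4
0.15,25,3840.0,3804.69,0.92
0.15,30,7050.0,7158.55,1.54
0.15,35,12100.0,12619.08,4.29
0.15,40,19600.0,19968.27,1.88
0.3,1,2.84,2.87,1.14
0.3,2,6.25,6.24,0.16
0.3,3,11.5,11.34,1.43
0.3,4,19.0,18.49,2.66
0.3,5,28.8,28.07,2.54
0.3,6,41.2,40.41,1.91
0.3,7,56.5,55.86,1.13
0.3,8,75.0,74.73,0.36
0.3,10,122.0,123.82,1.49
0.3,15,318.0,322.26,1.34
0.3,20,656.0,647.46,1.3
0.3,25,1180.0,1148.35,2.68
0.3,30,1930.0,1916.63,0.69
0.3,35,2950.0,2992.81,1.45
0.3,40,4280.0,4205.56,1.74
0.5,1,2.45,2.47,0.85
0.5,2,4.87,4.84,0.71
0.5,3,8.29,8.12,2.08
0.5,4,12.7,12.4,2.38
0.5,5,18.1,17.76,1.9
0.5,6,24.6,24.26,1.37
0.5,7,32.2,31.97,0.73
0.5,8,40.8,40.91,0.26
0.5,10,61.8,62.57,1.25
0.5,15,137.0,138.4,1.02
0.5,20,247.0,244.31,1.09
0.5,25,395.0,386.69,2.1
0.5,30,582.0,579.99,0.34
0.5,35,809.0,822.03,1.61
0.5,40,1080.0,1067.38,1.17
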