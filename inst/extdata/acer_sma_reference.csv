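pair,y,x,tree,n,r_squared,slope,slope_ci_low,slope_ci_high,cfs_pred,wbe_pred,intercept,intercept_ci_low,intercept_ci_high,rmse_cfs,rmse_wbe
SA~V,surface_area,volume,all,3484,0.995,0.756,0.754,0.758,0.750,0.625,0.742,0.735,0.750,0.006,0.131
L~D,length,diameter,all,3484,0.832,2.060,2.032,2.088,2.000,0.667,0.707,0.682,0.733,0.060,1.393
D~V,diameter,volume,all,3484,0.955,0.252,0.250,0.254,0.250,0.375,-0.171,-0.179,-0.163,0.002,0.123
L~V,length,volume,all,3484,0.957,0.519,0.515,0.522,0.500,0.250,0.355,0.340,0.370,0.019,0.269
D~SA,diameter,surface_area,all,3484,0.921,0.333,0.330,0.336,0.333,0.600,-0.418,-0.431,-0.406,0.000,0.267
L~SA,length,surface_area,all,3484,0.981,0.687,0.683,0.690,0.667,0.400,-0.154,-0.166,-0.142,0.020,0.287
SA~V,surface_area,volume,1,1016,0.996,0.745,0.742,0.748,0.750,0.625,0.793,0.780,0.806,0.005,0.120
SA~V,surface_area,volume,2,1554,0.995,0.761,0.758,0.764,0.750,0.625,0.731,0.719,0.742,0.008,0.128
SA~V,surface_area,volume,3,502,0.995,0.755,0.751,0.760,0.750,0.625,0.728,0.709,0.747,0.008,0.129
SA~V,surface_area,volume,4,412,0.995,0.763,0.757,0.768,0.750,0.625,0.694,0.671,0.718,0.009,0.131
L~D,length,diameter,1,1016,0.870,1.899,1.857,1.941,2.000,0.667,0.870,0.830,0.910,0.101,1.232
L~D,length,diameter,2,1554,0.821,2.137,2.092,2.182,2.000,0.667,0.675,0.637,0.714,0.120,1.356
L~D,length,diameter,3,502,0.837,2.054,1.982,2.128,2.000,0.667,0.648,0.582,0.714,0.103,1.367
L~D,length,diameter,4,412,0.815,2.170,2.081,2.262,2.000,0.667,0.534,0.450,0.617,0.123,1.402
D~V,diameter,volume,1,1016,0.968,0.261,0.258,0.264,0.250,0.375,-0.215,-0.228,-0.202,0.011,0.114
D~V,diameter,volume,2,1554,0.950,0.248,0.245,0.250,0.250,0.375,-0.161,-0.172,-0.150,0.008,0.121
D~V,diameter,volume,3,502,0.956,0.252,0.248,0.257,0.250,0.375,-0.156,-0.175,-0.136,0.007,0.122
D~V,diameter,volume,4,412,0.947,0.246,0.240,0.251,0.250,0.375,-0.127,-0.151,-0.104,0.006,0.124
L~V,length,volume,1,1016,0.965,0.495,0.490,0.501,0.500,0.250,0.462,0.436,0.487,0.005,0.245
L~V,length,volume,2,1554,0.956,0.529,0.524,0.535,0.500,0.250,0.332,0.309,0.354,0.021,0.263
L~V,length,volume,3,502,0.959,0.518,0.509,0.527,0.500,0.250,0.328,0.289,0.367,0.020,0.264
L~V,length,volume,4,412,0.955,0.534,0.523,0.545,0.500,0.250,0.257,0.211,0.304,0.024,0.269
D~SA,diameter,surface_area,1,1016,0.943,0.350,0.345,0.356,0.333,0.600,-0.493,-0.514,-0.472,0.017,0.250
D~SA,diameter,surface_area,2,1554,0.913,0.326,0.321,0.330,0.333,0.600,-0.399,-0.417,-0.380,0.013,0.262
D~SA,diameter,surface_area,3,502,0.923,0.334,0.326,0.342,0.333,0.600,-0.399,-0.430,-0.367,0.011,0.264
D~SA,diameter,surface_area,4,412,0.909,0.322,0.313,0.332,0.333,0.600,-0.351,-0.388,-0.314,0.011,0.267
L~SA,length,surface_area,1,1016,0.984,0.665,0.660,0.670,0.667,0.400,-0.066,-0.087,-0.045,0.002,0.265
L~SA,length,surface_area,2,1554,0.981,0.696,0.691,0.700,0.667,0.400,-0.176,-0.194,-0.158,0.020,0.281
L~SA,length,surface_area,3,502,0.982,0.686,0.677,0.694,0.667,0.400,-0.171,-0.202,-0.140,0.020,0.282
L~SA,length,surface_area,4,412,0.981,0.699,0.690,0.709,0.667,0.400,-0.228,-0.265,-0.191,0.024,0.287
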