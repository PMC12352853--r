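tree,measure,relative_likelihood,aicc_power_law,aicc_exponential,n
1,lengths,1.01e-182,16699.060,15860.929,1016
2,lengths,0,25533.535,23461.783,1554
3,lengths,1.13e-122,8089.437,7527.859,502
4,lengths,7.61e-82,6617.101,6243.537,412
1,diameters,1.01e-16,5585.737,5512.068,1016
2,diameters,0,9607.744,7700.496,1554
3,diameters,8.76e-28,2458.498,2583.102,502
4,diameters,2.35e-34,1998.699,2153.566,412
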