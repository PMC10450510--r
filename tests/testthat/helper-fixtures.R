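## Frozen fixtures for oracle comparisons.

## Samples whose D Agostino-Pearson K2 / p were computed with an
## independent reference implementation and frozen below.
dagoNormal40 <- c(-0.989121, -0.367787, 1.287925, 0.193974, 0.920231, 0.577104, 
    -0.636464, 0.541952, -0.316595, -0.322389, 0.097167, -1.52593, 
    1.192166, -0.67109, 1.000269, 0.136321, 1.532033, -0.659969, 
    -0.311795, 0.337769, -2.207471, 0.827921, 1.54163, 1.126807, 
    0.75477, -0.145978, 1.281902, 1.074031, 0.392621, 0.005114, -0.361767, 
    -1.230232, 1.226229, -2.172044, -0.370147, 0.16438, 0.859881, 
    1.761661, 0.993324, -0.291521)
dagoLognormal40 <- c(2.071199, 0.2832, 4.178442, 0.855153, 0.509789, 0.527788, 0.940483, 
    0.675174, 9.874048, 0.487638, 1.033145, 1.028447, 1.028676, 1.056906, 
    0.617817, 0.557994, 0.422249, 0.225784, 1.241483, 2.676142, 0.580954, 
    0.572001, 0.728708, 0.63088, 0.237813, 3.916146, 1.551155, 0.490812, 
    1.346046, 0.645031, 0.809258, 1.439022, 2.593386, 4.57005, 5.495389, 
    0.77969, 0.606683, 1.104726, 1.136943, 0.479879)
dagoUniform12 <- c(0.489988, 0.304361, 0.840822, 0.950476, 0.318875, 0.897768, 
    0.337529, 0.812112, 0.798844, 0.655285, 0.228703, 0.137674)
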