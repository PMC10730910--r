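eye_id,pupil_diameter_mm,z0,z1,z2,z3,z4,z5,z6,z7,z8,z9,z10,z11,z12,z13,z14,z15,z16,z17,z18,z19,z20,z21,z22,z23,z24,z25,z26,z27
eye001,2.714958698,          0,          0,          0,-0.07376202171,-0.219167036,0.04354965626,-0.167604805,0.06246012092,-0.02123438753,-0.0106860028,0.003577574332,-0.04243047171,0.07796277272,0.01935113285,-0.02166654977,-0.01324673313,0.006591213696,0.01866119648,0.013394543,0.02345953161,0.0151468621,          0,          0,          0,-0.00221100173,          0,          0,          0
eye002,5.573901259,          0,          0,          0,0.009176432125,-0.1020055887,-0.1572496736,-0.1180300181,0.05281329874,-0.02480921042,-0.03234568765,0.06649041264,0.006542788432,0.08256819214,-0.005757940081,0.004916840647,-0.0149421381,0.01021322034,0.01078520391,0.008510678966,-0.004437201409,0.02516909045,          0,          0,          0,0.004236182069,          0,          0,          0
eye003,6.050815018,          0,          0,          0,0.1078310422,0.1396853166,-0.08369092977,-0.04457445634,0.08149877211,-0.08900266504,-0.07124285962,-0.01194530984,-0.0004262821649,0.03854564604,-0.01408199588,0.03495816326,0.01623969651,0.009082793913,-0.01287970303,-7.065465538e-05,-0.008297391319,-0.02074398148,          0,          0,          0,0.001741706015,          0,          0,          0
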