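# {"shape":[3,3,3],"spacing_mm":[10,10,10],"origin_mm":[-10,-10,-10],"b0_axis":"x","source":"hand-written example map","created":"2026-09-29T12:00:00"}
x_mm,y_mm,z_mm,Bx_mT,By_mT,Bz_mT
-10,-10,-10,42.96000000000001,0.02,-0.01
0,-10,-10,43.010000000000005,0.02,-0.01
10,-10,-10,43.06,0.02,-0.01
-10,0,-10,42.940000000000005,0.02,-0.01
0,0,-10,42.99,0.02,-0.01
10,0,-10,43.04,0.02,-0.01
-10,10,-10,42.92,0.02,-0.01
0,10,-10,42.97,0.02,-0.01
10,10,-10,43.019999999999996,0.02,-0.01
-10,-10,0,42.970000000000006,0.02,-0.01
0,-10,0,43.02,0.02,-0.01
10,-10,0,43.07,0.02,-0.01
-10,0,0,42.95,0.02,-0.01
0,0,0,43.0,0.02,-0.01
10,0,0,43.05,0.02,-0.01
-10,10,0,42.93,0.02,-0.01
0,10,0,42.98,0.02,-0.01
10,10,0,43.029999999999994,0.02,-0.01
-10,-10,10,42.980000000000004,0.02,-0.01
0,-10,10,43.03,0.02,-0.01
10,-10,10,43.08,0.02,-0.01
-10,0,10,42.96,0.02,-0.01
0,0,10,43.01,0.02,-0.01
10,0,10,43.059999999999995,0.02,-0.01
-10,10,10,42.94,0.02,-0.01
0,10,10,42.989999999999995,0.02,-0.01
10,10,10,43.03999999999999,0.02,-0.01
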