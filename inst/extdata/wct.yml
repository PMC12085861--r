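# West Coast Tall preset. Physical constants and growth parameters follow
# the experimental set; taper anchor radii are synthetic field-realistic
# defaults (no measured anchors are published).
variety: WCT
rho: 600
g: 9.8
"Y": 1.14e+10
theta0: 0
a_v: 0.46
V_r: 0.01
s0: 0.01
s_param: 0.01
alpha: 0.001
theta_p: 1.5707963267948966
beta_max: 0
theta_pf: 1.9163715186897738
x_base: 0.175
x_dbh: 0.160
breast_height: 1.4
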