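# Chowghat Green Dwarf preset. The dwarf apical velocity and taper anchors
# are synthetic field-realistic defaults; the remaining constants follow the
# experimental set.
variety: CGD
rho: 600
g: 9.8
"Y": 1.14e+10
theta0: 0
a_v: 0.25
V_r: 0.01
s0: 0.01
s_param: 0.01
alpha: 0.001
theta_p: 1.5707963267948966
beta_max: 0
theta_pf: 1.9163715186897738
x_base: 0.150
x_dbh: 0.135
breast_height: 1.4
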