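# folding configuration
weight.cb_distance.short = 3
weight.cb_distance.medium = 3
weight.cb_distance.long = 4
weight.ca_distance.short = 2
weight.ca_distance.medium = 2
weight.ca_distance.long = 2.5
weight.cb_contact.short = 0.5
weight.cb_contact.medium = 0.5
weight.cb_contact.long = 1
weight.ca_contact.short = 0.5
weight.ca_contact.medium = 0.5
weight.ca_contact.long = 1
weight.omega.short = 1
weight.omega.medium = 1
weight.omega.long = 1.5
weight.theta.short = 1
weight.theta.medium = 1
weight.theta.long = 1.5
weight.phi_angle.short = 0.5
weight.phi_angle.medium = 0.5
weight.phi_angle.long = 1
weight.hb = 0.5
weight.vdw = 1
weight.tor = 0.3
m = 256
rounds = 10
steps = 2000
c1 = 0.0001
backtrack = 0.5
max_backtracks = 30
tol_e = 1e-06
tol_g = 1e-06
conv_window = 5
select_cutoff = 0.55
d_b = 8
init = random
seed = 0
hb_on = 1
vdw_on = 1
tor_on = 1
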