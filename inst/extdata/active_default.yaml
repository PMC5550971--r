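# Default constants of the active tension model (myofilament kinetics with
# fading-memory force-velocity response and a prescribed calcium transient).
# Rates in 1/ms, times in ms, T_req in kPa. These constants are inputs of
# the model, frozen here; they are not fitted.
T_req: 157.0
beta0: 4.9          # length dependence of developed tension
a_fv: 0.35          # curvature of the force-velocity relationship
A: [-29.0, 138.0, 129.0]      # fading-memory weights
alpha_Q: [0.03, 0.13, 0.625]  # fading-memory decay rates (1/ms)
alpha0: 0.01        # actin site binding rate scale (1/ms)
alpha_r1: 0.002     # linear unbinding rate (1/ms)
alpha_r2: 0.0017    # nonlinear relaxation rate (1/ms)
n_rel: 3.0          # nonlinear relaxation exponent
K_z: 0.15           # nonlinear relaxation half-point
n_hill: 2.0         # Hill exponent of calcium binding
ca50_ref: 0.5       # calcium half-activation at lambda_f = 1 (transient units)
beta1: 1.45         # length dependence of calcium sensitivity
ca_amp: 1.0         # calcium transient amplitude (normalized)
ca_tau: 60.0        # calcium transient time-to-peak (ms)
t_end_systole: 300.0  # end-systolic evaluation time after activation onset
dt: 1.0             # default integration step (ms)
dt_max: 5.0         # declared stability bound for the explicit integrator
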