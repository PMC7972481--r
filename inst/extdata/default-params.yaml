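# Default parameters of the sequence-learning network.  Every tunable used
# anywhere in the simulation lives here; code never hard-codes a value.
# Weight values are totals (per-synapse weight = total / n_pre), so behaviour
# is approximately independent of population size.

backend: spiking

network:
  n_columns: 12
  sizes:
    timer: 100
    timer_inh: 100
    messenger: 100
    messenger_inh: 100
  weights:
    spiking:
      w_tt0: 0.5        # weak random initial recurrent Timer weight (nS total)
      w_t_ti: 9         # Timer -> inhibitory (small, so inhibition dies first)
      w_ti_t: 0         # inhibitory feedback onto Timers (not needed: the
                        # saturating synaptic activation bounds the high state)
      w_tm: 18          # Timer -> Messenger (static W_EE^MT)
      w_im: 160         # inhibitory -> Messenger (static W_EI^MT)
      w_m_mi: 2         # Messenger -> inhibitory partner
      w_mi_m: 100       # inhibitory partner -> Messenger
      wta_t: 8          # soft WTA between foreign Timer populations
      wta_m: 15         # foreign Messenger -> local Messenger-inhibitory
      w_ff0: 0.2        # weak random initial feed-forward weight
      w_in: 8           # input-layer synapse weight per neuron (nS)
      w_in_mi: 8        # input drive to the Messenger-inhibitory partner (nS)
    rate:
      w_tt0: 0.15
      w_t_ti: 0.3
      w_ti_t: 0.0       # not needed: the transfer function bounds rates
      w_tm: 4.0
      w_im: 8.6
      w_m_mi: 0.05
      w_mi_m: 1.1
      wta_t: 0.06
      wta_m: 1.1        # foreign Messenger -> local Messenger-inhibitory
      w_ff0: 0.0
      w_in: 1.0         # scales protocol input_amp
      w_in_mi: 1.0      # input drive to the Messenger-inhibitory partner

neuron:                  # conductance-based LIF, excitatory populations
  C: 200                 # pF
  gL: 10                 # nS
  EL: -70                # mV
  EE: 0
  EI: -75
  vth: -54
  vth_jitter: 3          # per-neuron threshold spread (uniform, mV)
  vreset: -70
  tref: 2                # ms
  sigma: 1.3             # mV / sqrt(ms) voltage noise (fluctuation-driven
                         # firing; interspike-interval CV near 1)
  tau_s: 80              # ms, excitatory synaptic activation
  rho_syn: 0.3
  tau_r: 100             # ms, online rate estimator
  tau_s_in: 80

neuron_inh:
  tau_s: 10              # ms, inhibitory synaptic activation

rate:                    # rate backend transfer function and unit kinetics
  tau_u_exc: 80          # ms
  tau_u_inh: 10
  tau_u_mess: 25         # Messengers track their brief window quickly; the
                         # onset transient is shielded by feedforward inhibition
  theta: 1.0
  u_c: 10.0
  v_scale: 20.0

learning:
  spiking:
    recurrent:
      tau_p: 800         # ms
      tau_d: 267
      eta_p: 0.05        # 1/Hz^2
      eta_d: 0.05
      tmax_p: 1.0
      tmax_d: 1.03
      r_th: 25           # Hz
      eta_lr: 0.6
      trace_refractory: 25
      w_min: 0
      w_max: 7.5
    feedforward:
      tau_p: 400
      tau_d: 1200
      eta_p: 0.01
      eta_d: 0.002
      tmax_p: 1.0
      tmax_d: 1.3
      r_th: 14           # r_th_FF, above the spiking noise floor
      eta_lr: 2.0
      trace_refractory: 25
      w_min: 0
      w_max: 13.0
  rate:
    recurrent:
      tau_p: 800
      tau_d: 267
      eta_p: 0.05
      eta_d: 0.05
      tmax_p: 1.0
      tmax_d: 1.03
      r_th: 33
      eta_lr: 0.03
      trace_refractory: 25
      w_min: 0
      w_max: 0.4105
    feedforward:
      tau_p: 600         # long enough to survive the delay to the sequence-
      tau_d: 1800        # final reward that converts the last transition
      eta_p: 0.01
      eta_d: 0.001
      tmax_p: 1.0
      tmax_d: 1.3
      r_th: 10
      eta_lr: 0.1
      trace_refractory: 25
      w_min: 0
      w_max: 0.9

protocol:
  pulse_ms: 50
  peak_rate_hz: 800      # Poisson peak of the LGN-like input (spiking)
  input_amp: 50          # input amplitude during the pulse (rate backend)
  gap_ms: 4000           # inter-trial gap (long enough for traces to fade)
  n_trials: 80

nonmarkov:
  K: 150                 # reservoir units
  M: 400                 # sparse pattern units
  g: 0.9                 # reservoir gain (sd of W_res entries = g / sqrt(K))
  tau_net: 400           # ms
  j_scale: 0.15          # Messenger-to-reservoir drive scale, keeps the
                         # reservoir in the graded range of tanh so remnants
                         # of past pulses stay distinguishable
  theta_m: 15.0          # Messenger input threshold (Hz): gates patterns on
                         # genuine Messenger pulses, not residual transients
  theta_o: 0.055         # sparse unit threshold (top few percent of the
                         # sparse drive distribution under the g/sqrt(M) scale)
  rho_sparse: 0.04       # fraction of non-zero entries in O
  q_max: 6.0             # feedback weight ceiling
  q_rth: 35              # Timer rate threshold in the feedback Hebbian update
                         # (same noise-rejection role as r_th_FF)
  gap_ms: 3000           # longer gap so the reservoir state fades out
  wta_t: 0.06            # Timer competition in the three-stage variant
  feedback_during_training: false  # learned feedback is expressed at recall;
                         # during training the stimulus carries the sequence
                         # and live feedback destabilises joint learning
  tmax_d: 1.15           # stronger LTD saturation for repeated-element
                         # sequences: interior onsets act as extra rewards and
                         # their potentiation must be balanced (trial-sum
                         # fixed point)

measure:
  onset_frac: 0.5        # onset threshold as a fraction of the column peak
  offset_frac: 0.5
  debounce_ms: 50
  min_peak_hz: 5         # columns never exceeding this are marked absent
  duration_tol: 0.10     # per-element relative duration error for success
  convergence_tol: 0.02  # per-trial max relative weight change

sim:
  dt_spiking: 0.1        # ms
  dt_rate: 1.0
  trace_dt: 0.5          # eligibility-trace update interval (spiking)
  record_dt: 5.0         # rate-trace sampling interval
  rate_ceiling: 1000     # Hz, divergence guard

seed: 1
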