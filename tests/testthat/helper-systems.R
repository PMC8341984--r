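# canonical donor/DPA pairings used across tests
cfp_system <- function() donor_acceptor_system("CFP/DPA", r0 = 47)
yfp_system <- function() donor_acceptor_system("YFP/DPA", r0 = 36.5)

# noiseless fluorometry trace built directly from a normalized F-V relation:
# hold/step segments at 1 ms sampling, amplitude f0, plus constant background
build_fv_trace <- function(f_by_voltage, protocol = voltage_protocol(),
                           f0 = 1000, background = 0) {
  n_seg <- protocol$step_duration
  volts <- protocol$voltages
  seg_v <- as.vector(rbind(rep(protocol$v_hold, length(volts)), volts))
  v <- rep(rep(seg_v, each = n_seg), protocol$n_families)
  fvals <- ifelse(v == protocol$v_hold, 1, f_by_voltage[as.character(v)])
  data.frame(time_ms = seq_along(v) - 1,
             fluorescence = f0 * fvals + background,
             voltage_mV = v)
}
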