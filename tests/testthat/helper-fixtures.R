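# shared fixtures, all generated in code at test time

# noise-free model calibrated to the vehicle group's closed-form statistics
vehicle_model_quiet <- function(d_end = 0.019) {
  calibrate_failure_model(0.2422, m_end = 0.700, f0 = 0.126,
                          d_end = d_end, noise_sd = 0)
}

# short protocol for fast tests (30 trains, 3 superimposed)
short_protocol <- function(total = 30) stim_protocol(total_duration = total)

# a minimal hand-built nmj_stack around given channel volumes
manual_stack <- function(post, pre = post, pixel_size = 0.5, z_step = 2) {
  structure(
    list(post = post, pre = pre, pixel_size = pixel_size, z_step = z_step,
         channels = c("BTX", "SYN"),
         meta = list(fiber_diameter = 40, seed = NULL)),
    class = "nmj_stack"
  )
}
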