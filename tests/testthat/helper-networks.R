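# Helpers: build tiny reaction tables on the fly and an independent
# fixed-step reference integrator for oracle comparisons.

write_network_table <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  hdr <- "id\treactants\tproducts\tk\tk_units\tkind\tband_nm\tprovenance"
  writeLines(c(hdr, rows), path)
  path
}

tiny_network <- function(rows, ...) {
  load_network(write_network_table(rows), ...)
}

# network with only first-order singlet-oxygen decay
singlet_decay_network <- function(k = 2.9e5) {
  tiny_network(sprintf("8\t1O2\tO2\t%g\ts-1\temission\t1278\ttest", k))
}

# network with only hydroxyl-radical recombination
ho_recombination_network <- function(k = 5.5e9) {
  tiny_network(sprintf("5b\t2 HO.\tH2O2\t%g\tM-1 s-1\tbulk\tNA\ttest", k))
}

# classic fixed-step 4th-order Runge-Kutta, independent of deSolve
rk4 <- function(f, y0, t0, t1, dt) {
  n <- ceiling((t1 - t0) / dt)
  y <- y0
  t <- t0
  for (i in seq_len(n)) {
    h <- min(dt, t1 - t)
    k1 <- f(t, y)
    k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2)
    k4 <- f(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

# run simulate_pef with sources off in a single well-mixed box
simulate_closed <- function(net, init, t_end, output_dt,
                            mix_time = 0, rtol = 1e-8, atol = 1e-18) {
  sc <- pef_scenario("pb", mix_time = mix_time)
  sc$init <- init
  prof <- build_current_profile(pulse_protocol(), mode = "constant",
                                amplitude = 0)
  simulate_pef(net, sc, current_profile = prof, t_end = t_end,
               output_dt = output_dt, compartments = "single",
               rtol = rtol, atol = atol)
}
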