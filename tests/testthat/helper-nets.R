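# Trained networks are expensive; train each once per session and share
# across test files.
.net_cache <- new.env(parent = emptyenv())

trained_coal_net <- function() {
  if (is.null(.net_cache$coal)) {
    net <- nf_init(coal_model(), nf_config(hidden = 64L),
                   t_pilot = 110L, seed = 11)
    cfg <- nf_train_config(epochs = 20L, iter_per_epoch = 100L,
                           batch_size = 32L, t_range = c(110L, 110L))
    .net_cache$coal <- nf_train(net, cfg, seed = 12)
  }
  .net_cache$coal
}

trained_ddm_net <- function() {
  if (is.null(.net_cache$ddm)) {
    net <- nf_init(ddm_model(), nf_config(hidden = 64L),
                   t_pilot = 250L, n_pilot = 300L, seed = 21)
    cfg <- nf_train_config(epochs = 30L, iter_per_epoch = 100L,
                           batch_size = 32L, t_range = c(100L, 400L),
                           sim_dt = 2.5e-3)
    .net_cache$ddm <- nf_train(net, cfg, seed = 22)
  }
  .net_cache$ddm
}

# conjugate filtering sampler for the static Poisson model (Gamma-Poisson),
# optionally mean-shifted to serve as an SBC negative control
conjugate_poisson_sampler <- function(shift = 0) {
  function(series, checkpoints, n_draws) {
    nc <- length(checkpoints)
    th <- array(0, c(nc, n_draws, 1))
    cs <- cumsum(series$count)
    for (ci in seq_len(nc)) {
      t0 <- checkpoints[ci]
      th[ci, , 1] <- stats::rgamma(n_draws, shape = 1 + cs[t0],
                                   rate = 0.5 + t0) + shift
    }
    list(theta = th, eta = array(0, c(nc, n_draws, 0)))
  }
}
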