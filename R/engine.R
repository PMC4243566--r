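# Bridge between R state objects and the compiled engine. `.as_net_state`
# promotes a single-neuron state to the matrix layout; `.run_block` advances a
# state over a block of steps given an event list, either through the C++
# engine or the pure-R reference stepper (used for cross-checking).

.as_net_state <- function(state, params) {
  if (inherits(state, "skan_net_state")) return(state)
  st <- list(p = matrix(state$p, ncol = 1L), r = matrix(state$r, ncol = 1L),
             dr = matrix(state$dr, ncol = 1L), theta = state$theta,
             s = state$s, inh = 0L)
  class(st) <- "skan_net_state"
  st
}

# events: data.frame(time, channel) with 0-based times relative to block start,
# sorted by time. Returns list(state, s [neurons x n_steps], traces...).
.run_block <- function(state, events, n_steps, params, net,
                       adapt = TRUE, record_mem = FALSE, record_r = FALSE,
                       engine = "cpp") {
  stopifnot(inherits(state, "skan_net_state"))
  ev_t <- as.integer(events$time)
  ev_c <- as.integer(events$channel)
  if (is.unsorted(ev_t)) {
    o <- order(ev_t)
    ev_t <- ev_t[o]
    ev_c <- ev_c[o]
  }
  if (length(ev_t) && (ev_t[1] < 0L || ev_t[length(ev_t)] >= n_steps))
    stop("event times must lie within [0, n_steps)")
  if (engine == "cpp") {
    res <- .skan_engine_cpp(ev_t, ev_c, as.integer(n_steps), params$n_inputs,
                            state$p, state$r, state$dr,
                            state$s, as.integer(state$theta),
                            as.integer(state$inh),
                            params$w, params$ddr, params$dr_max,
                            params$dr_floor, params$theta_rise,
                            params$theta_fall,
                            net$inh_max, net$inh_decay,
                            adapt, record_mem, record_r)
    new_state <- state
    new_state$p <- res$p
    new_state$r <- res$r
    new_state$dr <- res$dr
    new_state$theta <- res$theta
    new_state$s <- res$s_last
    new_state$inh <- res$inh
    out <- list(state = new_state, s = res$s)
    if (record_mem) {
      out$membrane <- res$membrane
      out$theta_trace <- res$theta_trace
      out$inh_trace <- res$inh_trace
    }
    if (record_r) out$r_trace <- array(res$r_trace,
                                       dim = c(params$n_inputs,
                                               net$n_neurons, n_steps))
    return(out)
  }
  # pure-R reference path
  p_frozen <- params
  if (!adapt) p_frozen$ddr <- 0L
  nn <- net$n_neurons
  s_mat <- matrix(0L, nn, n_steps)
  mem_mat <- if (record_mem) matrix(0L, nn, n_steps)
  theta_mat <- if (record_mem) matrix(0L, nn, n_steps)
  inh_vec <- if (record_mem) integer(n_steps)
  r_arr <- if (record_r) array(0L, dim = c(params$n_inputs, nn, n_steps))
  st <- state
  theta_fixed <- st$theta
  ev_i <- 1L
  n_ev <- length(ev_t)
  u <- integer(params$n_inputs)
  for (t in seq_len(n_steps)) {
    u[] <- 0L
    while (ev_i <= n_ev && ev_t[ev_i] == t - 1L) {
      u[ev_c[ev_i]] <- 1L
      ev_i <- ev_i + 1L
    }
    st <- network_step(st, u, p_frozen, net)
    if (!adapt) st$theta <- theta_fixed
    s_mat[, t] <- st$s
    if (record_mem) {
      mem_mat[, t] <- colSums(st$r)
      theta_mat[, t] <- st$theta
      inh_vec[t] <- st$inh
    }
    if (record_r) r_arr[, , t] <- st$r
  }
  out <- list(state = st, s = s_mat)
  if (record_mem) {
    out$membrane <- mem_mat
    out$theta_trace <- theta_mat
    out$inh_trace <- inh_vec
  }
  if (record_r) out$r_trace <- r_arr
  out
}

# Rising edges of a binary row vector given the value preceding its first
# element; returns 1-based indices within the block.
.rising_edges <- function(s_row, s_before = 0L) {
  prev <- c(s_before, s_row[-length(s_row)])
  which(s_row == 1L & prev == 0L)
}
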