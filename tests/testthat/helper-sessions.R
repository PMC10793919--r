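# Session constructors shared across test files.

# One Q-learning session with an abrupt inverse-temperature change at a
# known trial (used by the particle-filter tracking checks).
pf_jump_session <- function(b_old, b_new, t_jump, n = 1000) {
  theta <- cbind(alpha = rep(0.4, n),
                 beta = c(rep(b_old, t_jump), rep(b_new, n - t_jump)))
  ex <- banditrnn:::.expand_task(task_validation())
  s <- banditrnn:::sim_session_cpp(0L, theta, as.integer(ex$block_id),
                                   ex$arm_left, ex$arm_right, FALSE, 0)
  tibble::tibble(subject = "j", block = ex$block_id, trial = ex$trial,
                 action = c("L", "R")[s$action + 1], reward = s$reward)
}
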