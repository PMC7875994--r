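# shared fixtures, built in code and cached per test run

.fixture_env <- new.env(parent = emptyenv())

# one full-length default session, reused wherever a realistic trial table
# is needed
default_session <- function() {
  if (is.null(.fixture_env$session))
    .fixture_env$session <- simulate_session(agent_params(),
                                             patch_dynamics_params(),
                                             seed = 11)
  .fixture_env$session
}

always_stay_agent <- function() agent_params(theta_leave = 1e9)
always_leave_agent <- function() agent_params(theta_leave = -1e9)

make_option_pair <- function(m = c(40, 20), p = c(0.7, 0.3)) {
  opt <- structure(list(m_left = m[1], m_right = m[2],
                        p_left = p[1], p_right = p[2],
                        no_brainer = "none", flipped = FALSE),
                   class = "option_pair")
  opt$no_brainer <- detect_no_brainer(opt)
  opt
}

# minimal hand-built trial table for arithmetic checks on the stats layer
tiny_trials <- function() {
  data.frame(
    trial = 1:6,
    cost = c(5, 5, 5, 15, 15, 15),
    mu_cur = 50, mu_alt = 50,
    val_cur = c(40, 42, 38, 35, 30, 60),
    val_alt = c(40, 80, 55, 50, 70, 45),
    side_cur = c("left", "left", "right", "right", "left", "left"),
    patch_choice = c("stay", "stay", "leave", "stay", "stay", "leave"),
    switch = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    m_left = c(10, 30, 20, 10, 12, 40),
    m_right = c(30, 12, 18, 25, 18, 20),
    p_left = c(0.5, 0.7, 0.3, 0.2, 0.6, 0.8),
    p_right = c(0.5, 0.3, 0.6, 0.8, 0.6, 0.4),
    no_brainer = c("none", "left", "none", "right", "right", "left"),
    flipped = FALSE,
    value_choice = c("right", "left", "right", "right", "right", "left"),
    rew_left = c(0, 30, 0, 0, 12, 40),
    rew_right = c(30, 0, 18, 25, 0, 0),
    reward = c(30, 30, 18, 25, 0, 40),
    rt_patch = c(0.8, 0.7, 1.1, 0.9, 0.85, 1.2),
    rt_value = c(1.4, 1.1, 1.6, 1.2, 1.3, 1.8),
    stringsAsFactors = FALSE
  )
}
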