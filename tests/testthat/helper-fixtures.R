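# Shared fixtures, built in code.

# Worked round-1 data: 26/63 control, 41/63 experimental (40% vs 65%).
r1_control <- function() binom_outcome(26, 63)
r1_experimental <- function() binom_outcome(41, 63)

# Round-2 concurrent data at the same nominal rates.
r2_control <- function() binom_outcome(7, 16)
r2_experimental <- function() binom_outcome(41, 63)

default_rule <- function() decision_rule(margin = 0.15, certainty = 0.60)

# Monte-Carlo oracle for P(p_e - p_c >= margin), independent of the
# quadrature path under test.
mc_prob_diff <- function(control, experimental, margin, n = 1e6) {
  pc <- rbeta(n, control$alpha, control$beta)
  pe <- rbeta(n, experimental$alpha, experimental$beta)
  p <- mean(pe - pc >= margin)
  list(p = p, se = sqrt(p * (1 - p) / n))
}

# A small design whose outcome grid is cheap to enumerate repeatedly.
small_design <- function(nc = 12, ne = 12, history = list())
  round_design("S", nc, ne, history = history)
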