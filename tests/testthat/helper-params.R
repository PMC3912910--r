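# Posterior point estimates used throughout as the reference parameter triple.
theta_star <- function() fgm_params(U = 0.01, n = 9, sigma = 0.034)

# Monte-Carlo standard error of a mean.
se_mean <- function(x) stats::sd(x) / sqrt(length(x))
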