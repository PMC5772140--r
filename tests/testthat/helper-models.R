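# shared fixtures, built in code

exp_delay <- function(rate) make_delay_distribution("exponential",
                                                    list(rate = rate))
fixed_delay <- function(sigma) make_delay_distribution("fixed",
                                                       list(sigma = sigma))
tnorm_delay <- function(mean = 2, sd = 0.75)
  make_delay_distribution("truncated_normal", list(mean = mean, sd = sd))

markov_mod <- function(beta = 0.3, gamma = 0.5)
  disease_model(exp_delay(beta), exp_delay(gamma))

powerlaw_gfs <- function()
  generating_functions(make_degree_distribution(
    "powerlaw_truncated", list(exponent = 2.5, kmin = 3, kmax = 60)))

regular_gfs <- function(k)
  generating_functions(make_degree_distribution("regular", list(k = k)))

star5 <- function() make_static_network(5, cbind(rep(0, 4), 1:4))

# numerical integral of a kernel's continuous part plus its atoms
kernel_mass <- function(fun, atoms, upper) {
  netsir:::integrate_with_breaks(fun, 0, upper, atoms$location) +
    sum(atoms$weight)
}
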