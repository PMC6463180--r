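# shared fixtures and independent oracles

chb <- preset_model("cHb")
hct <- preset_model("Hct")

# term-by-term arithmetic oracle for the mean surface: sums the five
# monomials explicitly, independent of evaluate_mean's vectorised form
oracle_mean <- function(p, ga, pna) {
  p <- unclass(p)
  total <- 0
  total <- total + p[[1]] * 1
  total <- total + p[[1]] * pna
  total <- total + p[[2]] * ga
  total <- total + p[[3]] * ga * ga
  total <- total + p[[4]] * ga * pna
  total <- total + p[[5]] * pna * pna
  total
}

random_surface <- function() {
  do.call(surface_parameters, as.list(stats::runif(5, -2, 2)))
}

# a random identifiable layout: jittered points spanning both ages
random_layout <- function(n = 40) {
  data.frame(ga = stats::runif(n, 22, 42), pna = stats::runif(n, 0, 28))
}

full_integer_grid <- function() expand.grid(ga = 22:42, pna = 0:28)

noise_free_grid <- function(model, layout = full_integer_grid()) {
  generate_grid(model, layout = layout, noise = noise_spec(0, 0, seed = 1))
}
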