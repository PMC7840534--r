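## Small fixtures built in code.

default_rates <- c(bumble = 0.55, honey = 0.25, leafcutting = 0.80)

## three plants x three species, hand-checkable
tiny_visits <- function() {
  data.frame(
    plant_id = rep(1:3, each = 3),
    species = rep(c("bumble", "honey", "leafcutting"), 3),
    flowers_visited = c(10, 10, 5,   7, 0, 0,   0, 0, 0))
}

tiny_plants <- function() {
  tm <- trait_model()
  p <- generate_plants(tm, 3, seed = 11)
  p$total_seeds <- c(100, 80, 40)
  p
}

## a full simulated study at modest size for structural tests
small_study <- function(n = 60, seed = 99) simulate_study(n_plants = n, seed = seed)
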