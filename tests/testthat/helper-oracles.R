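# Independent brute-force oracle for the pooled within-group mean
# square: explicit double loop over groups and members.
msw_bruteforce <- function(values, groups) {
  ssw <- 0
  df <- 0
  for (g in unique(groups)) {
    xs <- values[groups == g]
    if (length(xs) >= 2) {
      m <- sum(xs) / length(xs)
      for (x in xs) ssw <- ssw + (x - m)^2
      df <- df + length(xs) - 1
    }
  }
  ssw / df
}

# quick shoal_data builder from a list of per-shoal trait vectors
make_shoals <- function(values_list, trait = "length") {
  ids <- unlist(lapply(seq_along(values_list),
                       function(i) rep(i, length(values_list[[i]]))))
  v <- unlist(values_list)
  df <- data.frame(male_id = sprintf("m%03d", seq_along(v)),
                   shoal_id = ids,
                   length_mm = if (trait == "length") v else 25,
                   colour_score = if (trait == "colour") v else 0.05)
  shoal_data(df)
}

# field-like synthetic population: structure, phenotypes, assignment
field_like_population <- function(seed, assortment = 0,
                                  trait = "length") {
  st <- sample_shoal_structure(67, seed = seed)
  ph <- sample_male_phenotypes(sum(st$n_males),
                               field_phenotype_distribution(),
                               seed = seed + 1L)
  assign_males_to_shoals(ph, st, assortment = assortment,
                         trait = trait, seed = seed + 2L)
}
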