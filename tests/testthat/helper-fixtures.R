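# shared fixture builders; everything is generated in code under fixed seeds

tiny_schema <- function() {
  covariate_schema(
    individual = list(
      smoking = list(levels = c("never", "former", "current"),
                     reference = "never"),
      mvpa = list(levels = c("no", "yes"))),
    area = list(
      dist_pa_m = list(levels = c("T1", "T2", "T3"), reference = "T1")))
}

# n-row random dataset over `n_areas` areas matching tiny_schema()
tiny_dataset <- function(n = 200L, n_areas = 6L, seed = 42L) {
  set.seed(seed)
  ids <- sprintf("A%02d", seq_len(n_areas))
  rec <- data.frame(
    area_id = sample(ids, n, replace = TRUE),
    outcome = rbinom(n, 1L, 0.25),
    smoking = sample(c("never", "former", "current"), n, TRUE),
    mvpa = sample(c("no", "yes"), n, TRUE),
    stringsAsFactors = FALSE)
  ac <- data.frame(area_id = ids,
                   dist_pa_m = sample(c("T1", "T2", "T3"), n_areas, TRUE),
                   stringsAsFactors = FALSE)
  multilevel_dataset(rec, tiny_schema(), areas = ids, area_covariates = ac)
}

# assortment of small graphs used by the CAR oracle checks
oracle_graphs <- function() {
  path5 <- lattice_graph(1L, 5L, "p")
  cycle4 <- area_graph(cbind(c("c1", "c2", "c3", "c4"),
                             c("c2", "c3", "c4", "c1")),
                       paste0("c", 1:4))
  star5 <- area_graph(cbind(rep("s1", 4), paste0("s", 2:5)), paste0("s", 1:5))
  full4 <- area_graph(t(combn(paste0("f", 1:4), 2L)), paste0("f", 1:4))
  lat23 <- lattice_graph(2L, 3L, "l")
  lat24 <- lattice_graph(2L, 4L, "m")
  set.seed(7)
  rnd8 <- random_connected_graph(8L, seed = 7L)
  list(path5 = path5, cycle4 = cycle4, star5 = star5, full4 = full4,
       lat23 = lat23, lat24 = lat24, rnd8 = rnd8)
}

random_connected_graph <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("r%02d", seq_len(n))
  # random spanning tree plus a few extra edges
  from <- ids[vapply(2:n, function(i) sample(i - 1L, 1L), 1L)]
  to <- ids[2:n]
  extra <- t(replicate(n, sort(sample(n, 2L))))
  area_graph(rbind(cbind(from, to),
                   cbind(ids[extra[, 1L]], ids[extra[, 2L]])), ids)
}

# conditional moments of a joint Gaussian with (possibly singular)
# precision P: independent dense-linear-algebra oracle for the CAR
joint_conditional <- function(P, u, i, sigma2) {
  list(mean = -sum(P[i, -i] * u[-i]) / P[i, i],
       variance = sigma2 / P[i, i])
}
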