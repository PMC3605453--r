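#' Configuration for the generational population model
#'
#' A synchronised, constant-size population of virtual cells evolves over
#' discrete mitotic generations. At each mitosis a cell undergoes
#' whole-genome duplication with probability `t`, otherwise each chromosome
#' type independently loses one copy with probability `p` (an error-free
#' mitosis being the no-loss outcome). Cells with fewer than 2 copies of any
#' chromosome type (monosomy/nullisomy) or more than `max_N` chromosomes are
#' excluded from future generations; the next generation is restored to
#' `n_cells` by uniform resampling with replacement from the surviving
#' viable cells. Net growth is the fraction of cells retaining the
#' possibility of undergoing mitosis, i.e. the viable fraction.
#'
#' Defaults reflect measured rates in an unstable MYCN-amplified
#' neuroblastoma line: chromosome loss 4e-2 per chromosome per mitosis and
#' whole-genome duplication in ~6% of mitoses.
#'
#' @param p per-chromosome per-mitosis loss probability
#' @param t per-mitosis whole-genome duplication probability
#' @param n_cells population size
#' @param generations number of mitotic generations to simulate
#' @param max_N viability ceiling on total chromosome number
#' @param seed optional integer seed
#' @param wgd_enabled `FALSE` gives the control population that cannot
#'   duplicate its genome
#' @param n_types chromosome types per genome
#' @return a list of class `dynamics_config`
#' @export
dynamics_config <- function(p = 0.04, t = 0.06, n_cells = 10000L,
                            generations = 500L, max_N = 92L, seed = NULL,
                            wgd_enabled = TRUE, n_types = 23L) {
  stopifnot(p >= 0, p <= 1, t >= 0, t <= 1, n_cells >= 1L,
            generations >= 1L)
  structure(list(p = p, t = t, n_cells = as.integer(n_cells),
                 generations = as.integer(generations),
                 max_N = as.integer(max_N), seed = seed,
                 wgd_enabled = isTRUE(wgd_enabled),
                 n_types = as.integer(n_types)),
            class = "dynamics_config")
}

#' Advance the population by one mitotic generation
#'
#' @param population integer matrix, cells in rows, chromosome types in
#'   columns; all cells must be viable
#' @param config a [dynamics_config()]
#' @return list: `population` (resampled back to `n_cells` viable cells),
#'   `net_growth` (viable fraction after this generation's events),
#'   `excluded_monosomy` and `excluded_polyploidy` (counts)
#' @export
step_generation <- function(population, config) {
  n <- nrow(population)
  if (!n) stop("empty population")
  if (config$wgd_enabled && config$t > 0) {
    wgd <- stats::runif(n) < config$t
  } else {
    wgd <- rep(FALSE, n)
  }
  if (any(wgd))
    population[wgd, ] <- 2L * population[wgd, , drop = FALSE]
  n_loss <- sum(!wgd)
  if (n_loss && config$p > 0) {
    losses <- matrix(stats::rbinom(n_loss * config$n_types, 1L, config$p),
                     nrow = n_loss)
    population[!wgd, ] <- population[!wgd, , drop = FALSE] - losses
  }
  mono <- apply(population, 1L, min) <= 1L
  high <- rowSums(population) > config$max_N
  viable <- !mono & !high
  net_growth <- mean(viable)
  if (!any(viable))
    stop("population extinct: no viable cells remain")
  idx <- which(viable)
  keep <- idx[sample.int(length(idx), config$n_cells, replace = TRUE)]
  list(population = population[keep, , drop = FALSE],
       net_growth = net_growth,
       excluded_monosomy = sum(mono), excluded_polyploidy = sum(high & !mono))
}

#' Run the chromosome-loss / whole-genome-duplication population model
#'
#' Evolves `n_cells` diploid cells for `generations` mitotic generations
#' under the rules of [dynamics_config()], recording per generation the
#' histogram of total chromosome number over the (viable, resampled)
#' population, its mean, the modal chromosome number, and the net-growth
#' fraction. Seeded runs are reproducible.
#'
#' @param config a [dynamics_config()]
#' @return an object of class `cn_trajectory`: list with `summary` (data
#'   frame: generation, mean_N, modal_N, net_growth,
#'   excluded_monosomy, excluded_polyploidy), `hist` (generations x N
#'   matrix of cell counts), and `config`
#' @export
run_dynamics <- function(config = dynamics_config()) {
  stopifnot(inherits(config, "dynamics_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pop <- matrix(2L, nrow = config$n_cells, ncol = config$n_types)
  G <- config$generations
  hist <- matrix(0L, nrow = G, ncol = config$max_N,
                 dimnames = list(NULL, seq_len(config$max_N)))
  mean_N <- modal_N <- net_growth <- numeric(G)
  ex_mono <- ex_poly <- integer(G)
  for (g in seq_len(G)) {
    step <- tryCatch(step_generation(pop, config), error = function(e)
      stop("extinction at generation ", g, ": ", conditionMessage(e)))
    pop <- step$population
    Ns <- rowSums(pop)
    tab <- tabulate(Ns, nbins = config$max_N)
    hist[g, ] <- tab
    mean_N[g] <- mean(Ns)
    modal_N[g] <- which.max(tab)
    net_growth[g] <- step$net_growth
    ex_mono[g] <- step$excluded_monosomy
    ex_poly[g] <- step$excluded_polyploidy
  }
  structure(list(
    summary = data.frame(generation = seq_len(G), mean_N = mean_N,
                         modal_N = modal_N, net_growth = net_growth,
                         excluded_monosomy = ex_mono,
                         excluded_polyploidy = ex_poly),
    hist = hist, config = config), class = "cn_trajectory")
}

#' @export
print.cn_trajectory <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<cn_trajectory %d cells x %d generations (p=%g, ",
                     "t=%g%s)>\n  final mean N = %.1f, mean net growth = ",
                     "%.3f\n"),
              x$config$n_cells, x$config$generations, x$config$p,
              x$config$t,
              if (x$config$wgd_enabled) "" else ", WGD disabled",
              s$mean_N[nrow(s)], mean(s$net_growth)))
  invisible(x)
}
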