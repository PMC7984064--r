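# Seeded generator of synthetic immunogold point fields: a Poisson cluster
# (Thomas-type) process with an apical-to-basal density gradient, a
# homogeneous scattered component, label displacement and partial labeling
# efficiency, with configuration ground truth exported alongside.

#' Parameters for the synthetic immunolabel field generator
#'
#' The field is a rectangular membrane sheet with the apical edge at axial
#' position 0 and the basal edge at `field_size_um[1]`. Cluster parents are
#' drawn from an inhomogeneous Poisson process whose intensity decays
#' exponentially with distance from the apical edge; each parent emits a
#' Poisson number of labels scattered isotropically around it (a Thomas
#' process). A homogeneous Poisson field of scattered single labels is
#' added. Every label is then displaced uniformly within a disc -- the
#' epitope-to-gold offset introduced by the primary/secondary antibody
#' bridge, up to about 20 nm -- and retained with the labeling efficiency.
#'
#' @param field_size_um length (apical to basal) and width of the sheet, µm.
#' @param parent_intensity cluster parents per µm² at the apical edge.
#' @param offspring_mean mean labels per parent (Poisson).
#' @param offspring_sigma_nm isotropic Gaussian scatter of labels around
#'   their parent, nm.
#' @param gradient_decay_um exponential decay length of the parent intensity
#'   with apical distance (`Inf` = uniform).
#' @param scattered_intensity homogeneous single-label intensity per µm².
#' @param label_displacement_max_nm radius of the uniform-in-disc label
#'   displacement (default 20 nm).
#' @param labeling_efficiency Bernoulli retention probability in [0, 1].
#' @param seed mandatory RNG seed.
#' @return Validated parameter list of class `field_sim_params`.
#' @export
field_sim_params <- function(field_size_um = c(10, 10),
                             parent_intensity = 1,
                             offspring_mean = 5,
                             offspring_sigma_nm = 15,
                             gradient_decay_um = Inf,
                             scattered_intensity = 1,
                             label_displacement_max_nm = 20,
                             labeling_efficiency = 1,
                             seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  field_size_um <- as.numeric(field_size_um)
  if (length(field_size_um) == 1L) field_size_um <- rep(field_size_um, 2L)
  if (any(field_size_um <= 0)) stop("field_size_um must be positive")
  stopifnot(parent_intensity >= 0, offspring_mean >= 0, offspring_sigma_nm >= 0,
            gradient_decay_um > 0, scattered_intensity >= 0,
            label_displacement_max_nm >= 0,
            labeling_efficiency >= 0, labeling_efficiency <= 1)
  structure(list(field_size_um = field_size_um,
                 parent_intensity = parent_intensity,
                 offspring_mean = offspring_mean,
                 offspring_sigma_nm = offspring_sigma_nm,
                 gradient_decay_um = gradient_decay_um,
                 scattered_intensity = scattered_intensity,
                 label_displacement_max_nm = label_displacement_max_nm,
                 labeling_efficiency = labeling_efficiency,
                 seed = as.integer(seed)),
            class = "field_sim_params")
}

#' Simulate a synthetic immunogold particle field with ground truth
#'
#' See [field_sim_params()] for the generative model. The truth class of
#' every label ("configuration truth") is obtained by applying the same
#' 55 nm single-linkage rule ([link_particles()]) to the noiseless,
#' pre-displacement, pre-thinning label configuration, so recovery tests
#' measure exactly the effect of displacement, partial labeling and
#' clipping. Parents may fall up to three offspring sigmas outside the
#' field (plus-sampling) so edge intensity is unbiased; labels outside the
#' field after displacement are clipped out and removed from the truth.
#'
#' @param params a [field_sim_params()] object.
#' @param truth_dmax_nm linkage threshold used for configuration truth
#'   (default 55 nm).
#' @return List with `particles` (a [particle_set] of retained labels, nm,
#'   with rectangular analysed region and apical/basal edges) and `truth`:
#'   `parents_nm`, per retained label its `parent` (index or `NA` for the
#'   scattered component), `truth_class` (scattered/doublet/cluster from the
#'   configuration linkage), pre-displacement coordinates, class fractions
#'   over retained labels, and a parameter echo.
#' @export
simulate_particle_field <- function(params, truth_dmax_nm = 55) {
  stopifnot(inherits(params, "field_sim_params"))
  set.seed(params$seed)
  L <- params$field_size_um[1] * 1000  # axial extent, nm
  W <- params$field_size_um[2] * 1000
  margin <- 3 * params$offspring_sigma_nm

  # parents: homogeneous candidates on the margin-extended window, thinned
  # by the apical-distance gradient (capped at the apical-edge intensity
  # outside the cell)
  ext_area_um2 <- (L + 2 * margin) * (W + 2 * margin) / 1e6
  n_par <- stats::rpois(1, params$parent_intensity * ext_area_um2)
  par_x <- stats::runif(n_par, -margin, L + margin)
  par_y <- stats::runif(n_par, -margin, W + margin)
  if (is.finite(params$gradient_decay_um)) {
    keep_p <- exp(-pmax(par_x, 0) / (params$gradient_decay_um * 1000))
    keep <- stats::runif(n_par) < keep_p
    par_x <- par_x[keep]; par_y <- par_y[keep]
    n_par <- length(par_x)
  }

  # offspring labels
  n_off <- if (n_par > 0) stats::rpois(n_par, params$offspring_mean) else integer()
  parent_of <- rep(seq_len(n_par), n_off)
  off_x <- par_x[parent_of] + stats::rnorm(length(parent_of), 0, params$offspring_sigma_nm)
  off_y <- par_y[parent_of] + stats::rnorm(length(parent_of), 0, params$offspring_sigma_nm)

  # scattered singles (homogeneous over the field itself)
  n_sc <- stats::rpois(1, params$scattered_intensity * L * W / 1e6)
  sc_x <- stats::runif(n_sc, 0, L)
  sc_y <- stats::runif(n_sc, 0, W)

  x0 <- c(off_x, sc_x)
  y0 <- c(off_y, sc_y)
  parent <- c(parent_of, rep(NA_integer_, n_sc))
  n_all <- length(x0)

  # configuration truth: linkage on the pre-displacement, pre-thinning field
  truth_class <- character(0)
  if (n_all > 0) {
    memb <- link_particles(cbind(x0, y0), dmax_nm = truth_dmax_nm)
    sizes <- table(memb$group)
    truth_class <- group_class(as.integer(sizes[as.character(memb$group)]))
  }

  # displacement (uniform in disc), thinning, clipping
  if (n_all > 0) {
    r <- params$label_displacement_max_nm * sqrt(stats::runif(n_all))
    th <- stats::runif(n_all, 0, 2 * pi)
    x1 <- x0 + r * cos(th)
    y1 <- y0 + r * sin(th)
    retained <- stats::runif(n_all) < params$labeling_efficiency
    inside <- x1 >= 0 & x1 <= L & y1 >= 0 & y1 <= W
    keep <- retained & inside
  } else {
    x1 <- y1 <- numeric()
    keep <- logical()
  }

  region <- cbind(c(0, L, L, 0), c(0, 0, W, W))
  particles <- particle_set(x1[keep], y1[keep],
                            analyzed_region = region,
                            apical_edge = c(0, W / 2), basal_edge = c(L, W / 2),
                            source = "frl")
  cls <- factor(truth_class[keep], levels = c("scattered", "doublet", "cluster"))
  frac <- if (any(keep)) as.numeric(table(cls)) / sum(keep) else rep(NaN, 3L)
  names(frac) <- c("scattered", "doublet", "cluster")
  list(particles = particles,
       truth = list(parents_nm = cbind(x = par_x, y = par_y),
                    parent = parent[keep],
                    truth_class = as.character(cls),
                    pre_displacement_nm = cbind(x = x0[keep], y = y0[keep]),
                    class_fractions = frac,
                    n_configuration = n_all,
                    params = params))
}
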