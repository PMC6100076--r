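# Seeded synthetic fixtures emulating the statistical structure of a small
# P-gp efflux-ratio QSAR study: a seven-descriptor menu (surface area,
# molecular volume, polar surface area, hydrogen-bond donor count,
# rotatable-bond count, aromatic-ring count, nitrogen+oxygen count), two
# deliberately collinear companions (a molecular-weight column tracking
# volume, a hydrogen-bond-acceptor column tracking the N+O count), and a
# log ER response that rises then falls with the donor count (peaking at 6)
# and with the lipophilicity proxy. Only the qualitative shape of those
# relationships is encoded, never any real compound's values.

#' Specification of a synthetic efflux-ratio dataset
#'
#' @param n_samples number of pseudo-molecules (>= 10; default 200).
#' @param noise_sd Gaussian noise on log ER, in log units (default 0.1).
#' @param seed integer seed.
#' @param hbd_peak donor count at which mean log ER peaks (default 6).
#' @param hbd_width Gaussian width of the donor bump (default 2).
#' @param lip_peak aromatic-ring count (lipophilicity proxy) at the log ER
#'   peak (default 3).
#' @param lip_width width of the lipophilicity bump (default 1.5).
#' @param amp_hbd,amp_lip bump amplitudes in log ER units.
#' @param size_slope linear coefficient of the (scaled) molecular volume.
#' @param include_collinear add the MW-like and HBA-like collinear
#'   companions (default TRUE; the intercorrelation filter is expected to
#'   remove them).
#' @param collinear_r2 target squared correlation of MW-like vs Vm-like
#'   and HBA-like vs nNO-like columns (default 0.98).
#' @return a \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_samples = 200, noise_sd = 0.1, seed = 1L,
                           hbd_peak = 6, hbd_width = 2, lip_peak = 3,
                           lip_width = 1.5, amp_hbd = 1.0, amp_lip = 0.6,
                           size_slope = 0.3, include_collinear = TRUE,
                           collinear_r2 = 0.98) {
  stopifnot(n_samples >= 10, noise_sd >= 0)
  structure(list(n_samples = n_samples, noise_sd = noise_sd, seed = seed,
                 hbd_peak = hbd_peak, hbd_width = hbd_width,
                 lip_peak = lip_peak, lip_width = lip_width,
                 amp_hbd = amp_hbd, amp_lip = amp_lip,
                 size_slope = size_slope,
                 include_collinear = include_collinear,
                 collinear_r2 = collinear_r2),
            class = "synthetic_spec")
}

# Noise-free response surface: two inverted-U (Gaussian bump) terms plus a
# linear size term. Exposed for tests that need analytic expectations.
synthetic_surface <- function(spec, hbd, n_ar, vm) {
  spec$amp_hbd * exp(-(hbd - spec$hbd_peak)^2 / (2 * spec$hbd_width^2)) +
    spec$amp_lip * exp(-(n_ar - spec$lip_peak)^2 / (2 * spec$lip_width^2)) +
    spec$size_slope * (vm - 500) / 150
}

#' Generate a synthetic efflux-ratio dataset
#'
#' Draws the descriptor menu and computes log ER = f(descriptors) + noise,
#' where f carries an inverted-U dependence on the donor count (rise up to
#' the configured peak, fall beyond), an inverted-U in the aromatic-ring
#' lipophilicity proxy, and a linear molecular-size term. The generative
#' descriptors are HBD, nAr and Vm; SA, PSA, nRot and nNO are inactive
#' context, and the optional MW/HBA companions are collinear duplicates
#' the filtering stage should discard.
#'
#' @param spec a \code{synthetic_spec}.
#' @return list: \code{molecules} (data.frame id, er, log_er),
#'   \code{table} (a \code{descriptor_table} with response),
#'   \code{active} (names of the generative descriptors).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples
  with_substream(spec$seed, "synthetic", 0L, {
    vm <- stats::rnorm(n, 500, 150)
    vm <- pmax(vm, 100)
    sa <- 0.9 * vm + stats::rnorm(n, 0, 120)      # second size metric
    sa <- pmax(sa, 50)
    psa <- pmax(stats::rnorm(n, 90, 35), 0)
    hbd <- stats::rbinom(n, 10, 0.4)              # integers 0..10
    n_rot <- pmin(stats::rpois(n, 5), 15L)
    n_ar <- stats::rbinom(n, 6, 0.45)             # integers 0..6
    n_no <- pmin(stats::rpois(n, 4), 12L)

    mat <- cbind(SA = sa, Vm = vm, PSA = psa, HBD = hbd, nRot = n_rot,
                 nAr = n_ar, nNO = n_no)
    if (spec$include_collinear) {
      mw <- collinear_companion(vm, spec$collinear_r2)
      hba <- pmax(round(collinear_companion(n_no, spec$collinear_r2,
                                            scale = 1)), 0)
      mat <- cbind(mat, MW = mw, HBA = hba)
    }
    rownames(mat) <- sprintf("mol%03d", seq_len(n))

    f <- synthetic_surface(spec, hbd, n_ar, vm)
    log_er <- f + stats::rnorm(n, 0, spec$noise_sd)
    molecules <- data.frame(id = rownames(mat), er = 10^log_er,
                            log_er = log_er, stringsAsFactors = FALSE)
    list(molecules = molecules,
         table = descriptor_table(mat, log_er),
         active = c("HBD", "nAr", "Vm"))
  })
}

# Companion column with a target squared correlation to x, drawn under the
# caller's RNG state.
collinear_companion <- function(x, target_r2, scale = 0.55) {
  stopifnot(target_r2 > 0, target_r2 < 1)
  signal <- scale * x
  noise_sd <- stats::sd(signal) * sqrt((1 - target_r2) / target_r2)
  signal + stats::rnorm(length(x), 0, noise_sd)
}

#' Generate a pair of descriptors with a target intercorrelation
#'
#' @param n number of samples.
#' @param target_r2 target squared Pearson correlation in (0, 1).
#' @param seed integer seed.
#' @return a \code{descriptor_table} with columns x1, x2 (no response);
#'   realized r2 is within about 0.03 of the target for n >= 500.
#' @export
generate_collinear_pair <- function(n = 500, target_r2 = 0.98, seed = 1L) {
  stopifnot(target_r2 > 0, target_r2 < 1)
  with_substream(seed, "collinear_pair", 0L, {
    x1 <- stats::rnorm(n)
    x2 <- collinear_companion(x1, target_r2, scale = 1)
    descriptor_table(cbind(x1 = x1, x2 = x2))
  })
}
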