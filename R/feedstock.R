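#' Crude carbohydrate content by difference
#'
#' Computes crude carbohydrates (XC) from the other Weender fractions by
#' closure of the organic matter balance: XC = 1000 - XA - XP - XL, all in
#' g per kg total solids (TS).
#'
#' @param xa Crude ash, g per kg TS.
#' @param xp Crude protein, g per kg TS.
#' @param xl Crude lipid, g per kg TS.
#' @return Crude carbohydrates, g per kg TS. Vectorised over its arguments.
#' @examples
#' crude_carbohydrates(150.0, 123.7, 27.0)  # deep litter: 699.3
#' @export
crude_carbohydrates <- function(xa, xp, xl) {
  for (nm in c("xa", "xp", "xl")) {
    v <- get(nm)
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop("'", nm, "' must be finite numeric", call. = FALSE)
    }
    if (any(v < 0)) stop("'", nm, "' must be >= 0", call. = FALSE)
    if (any(v > 1000)) stop("'", nm, "' exceeds 1000 g per kg TS", call. = FALSE)
  }
  s <- xa + xp + xl
  if (any(s > 1000)) {
    stop("xa + xp + xl exceeds 1000 g per kg TS", call. = FALSE)
  }
  1000 - s
}

#' Crude protein from Kjeldahl nitrogen
#'
#' Crude protein (XP) is estimated from organic nitrogen (total N minus
#' inorganic N) with the conventional 6.25 protein-to-nitrogen factor.
#'
#' @param total_n Total nitrogen, g per kg TS.
#' @param inorganic_n Inorganic (ammonium) nitrogen, g per kg TS.
#' @return Crude protein, g per kg TS.
#' @export
crude_protein_from_nitrogen <- function(total_n, inorganic_n) {
  if (any(inorganic_n < 0) || any(total_n < 0)) {
    stop("nitrogen contents must be >= 0", call. = FALSE)
  }
  if (any(inorganic_n > total_n)) {
    stop("inorganic_n exceeds total_n", call. = FALSE)
  }
  (total_n - inorganic_n) * 6.25
}

#' Describe one feedstock's proximate composition
#'
#' Bundles the proximate (Weender) characterisation of a substrate: total
#' solids as a percentage of fresh matter, volatile solids as a percentage of
#' TS, the crude fractions XA/XC/XP/XL in g per kg TS, optional fibre
#' fractions (XF, ADF, NDF, ADL) and an optional carbohydrate degradability
#' quotient. The Weender fractions should close to 1000 g per kg TS; a
#' violation beyond \code{closure_tol} raises a warning (printed literature
#' tables do not always close exactly), never an error.
#'
#' @param name Feedstock label; used to match feeding-schedule columns.
#' @param ts_pct_fm Total solids, \% of fresh matter.
#' @param vs_pct_ts Volatile solids, \% of TS.
#' @param xa,xc,xp,xl Crude ash/carbohydrates/protein/lipid, g per kg TS.
#' @param xf,adf,ndf,adl Optional fibre fractions, g per kg TS.
#' @param dq_xc Optional degradability quotient of crude carbohydrates,
#'   fraction in [0, 1].
#' @param nh4n,vfa_acetic,vfa_propionic,vfa_butyric,vfa_valeric,lactic
#'   Optional soluble analytes (g/L as printed in source tables); carried as
#'   metadata, not used by the influent transformation.
#' @param composition_sd Optional named numeric vector of standard deviations
#'   for perturbation (e.g. \code{c(ts_pct_fm = 1.4)}).
#' @param closure_tol Allowed absolute deviation of xa+xc+xp+xl from 1000
#'   g per kg TS before a warning is raised (default 10).
#' @return An object of class \code{feedstock_spec}.
#' @export
feedstock_spec <- function(name, ts_pct_fm, vs_pct_ts, xa, xc, xp, xl,
                           xf = NA_real_, adf = NA_real_, ndf = NA_real_,
                           adl = NA_real_, dq_xc = NA_real_,
                           nh4n = NA_real_, vfa_acetic = NA_real_,
                           vfa_propionic = NA_real_, vfa_butyric = NA_real_,
                           vfa_valeric = NA_real_, lactic = NA_real_,
                           composition_sd = NULL, closure_tol = 10) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  chk_range <- function(v, nm, lo, hi) {
    if (!is.na(v) && (v < lo || v > hi)) {
      stop("'", nm, "' of feedstock '", name, "' outside [", lo, ", ", hi, "]",
           call. = FALSE)
    }
  }
  chk_range(ts_pct_fm, "ts_pct_fm", 0, 100)
  chk_range(vs_pct_ts, "vs_pct_ts", 0, 100)
  for (nm in c("xa", "xc", "xp", "xl", "xf", "adf", "ndf", "adl")) {
    chk_range(get(nm), nm, 0, 1000)
  }
  chk_range(dq_xc, "dq_xc", 0, 1)
  if (!any(is.na(c(adl, adf, ndf))) && !(adl <= adf && adf <= ndf)) {
    stop("fibre fractions of '", name, "' must satisfy adl <= adf <= ndf",
         call. = FALSE)
  }
  closure <- xa + xc + xp + xl
  if (abs(closure - 1000) > closure_tol) {
    warning("Weender fractions of '", name, "' sum to ",
            format(closure, digits = 6),
            " g per kg TS (closure violated by ",
            format(closure - 1000, digits = 4), ")", call. = FALSE)
  }
  structure(
    list(name = name, ts_pct_fm = ts_pct_fm, vs_pct_ts = vs_pct_ts,
         xa = xa, xc = xc, xp = xp, xl = xl,
         xf = xf, adf = adf, ndf = ndf, adl = adl, dq_xc = dq_xc,
         nh4n = nh4n, vfa_acetic = vfa_acetic, vfa_propionic = vfa_propionic,
         vfa_butyric = vfa_butyric, vfa_valeric = vfa_valeric,
         lactic = lactic, composition_sd = composition_sd),
    class = "feedstock_spec"
  )
}

#' @export
print.feedstock_spec <- function(x, ...) {
  cat("Feedstock:", x$name, "\n")
  cat(sprintf("  TS %.1f %% FM, VS %.1f %% TS\n", x$ts_pct_fm, x$vs_pct_ts))
  cat(sprintf("  XA %.1f  XC %.1f  XP %.1f  XL %.1f  (g per kg TS)\n",
              x$xa, x$xc, x$xp, x$xl))
  if (!is.na(x$dq_xc)) cat(sprintf("  DQ_XC %.2f\n", x$dq_xc))
  if (!is.na(x$adl)) cat(sprintf("  ADL %.1f g per kg TS\n", x$adl))
  invisible(x)
}

#' Read a feedstock characterisation table
#'
#' Reads a comma-separated table with headers
#' \code{name,ts_pct_fm,vs_pct_ts,xa,xc,xp,xl,xf,adf,ndf,adl,dq_xc}
#' (empty cell = missing) into a named list of \code{\link{feedstock_spec}}
#' objects.
#'
#' Because XC is defined by difference, each row's printed XC is also checked
#' against \code{1000 - XA - XP - XL}; a deviation beyond \code{xc_check_tol}
#' raises a "closure violated" warning naming the feedstock (known to occur
#' for literature cattle-manure characterisations), never an error.
#'
#' @param path Path to the CSV file.
#' @param closure_tol Passed to \code{\link{feedstock_spec}}.
#' @param xc_check_tol Allowed deviation of the printed XC from the
#'   by-difference value, g per kg TS (default 0.5, i.e. printed precision).
#' @return A named list of \code{feedstock_spec}, class \code{feedstock_set}.
#' @export
read_feedstock_table <- function(path, closure_tol = 10, xc_check_tol = 0.5) {
  if (!file.exists(path)) stop("feedstock table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "ts_pct_fm", "vs_pct_ts", "xa", "xc", "xp", "xl")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("feedstock table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  opt <- c("xf", "adf", "ndf", "adl", "dq_xc")
  for (nm in opt) if (is.null(tab[[nm]])) tab[[nm]] <- NA_real_
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    feedstock_spec(
      name = tab$name[i], ts_pct_fm = tab$ts_pct_fm[i],
      vs_pct_ts = tab$vs_pct_ts[i],
      xa = tab$xa[i], xc = tab$xc[i], xp = tab$xp[i], xl = tab$xl[i],
      xf = as.numeric(tab$xf[i]), adf = as.numeric(tab$adf[i]),
      ndf = as.numeric(tab$ndf[i]), adl = as.numeric(tab$adl[i]),
      dq_xc = as.numeric(tab$dq_xc[i]), closure_tol = closure_tol
    )
  })
  names(specs) <- tab$name
  xc_diff <- tab$xc - (1000 - tab$xa - tab$xp - tab$xl)
  for (i in which(abs(xc_diff) > xc_check_tol)) {
    warning("crude carbohydrates of '", tab$name[i], "': printed XC = ",
            tab$xc[i], " but 1000 - XA - XP - XL = ",
            format(1000 - tab$xa[i] - tab$xp[i] - tab$xl[i], digits = 6),
            "; closure violated by ", format(xc_diff[i], digits = 4),
            " g per kg TS (stored as printed)", call. = FALSE)
  }
  structure(specs, class = "feedstock_set")
}

#' Packaged feedstock characterisation of the studied plant
#'
#' Returns the eight-feedstock proximate characterisation used throughout the
#' package (cattle manure, deep litter, maize and grass silage, meadow grass,
#' fresh grass, straw, animal feed waste). The cattle-manure row reproduces
#' its literature source verbatim and is known to violate exact Weender
#' closure; loading it therefore emits a validation warning unless
#' \code{quiet = TRUE}.
#'
#' @param quiet Suppress the documented closure warning (default TRUE).
#' @return A \code{feedstock_set}.
#' @export
plant_feedstocks <- function(quiet = TRUE) {
  path <- system.file("extdata", "feedstocks_plant.csv",
                      package = "biogasbench", mustWork = TRUE)
  if (quiet) {
    suppressWarnings(read_feedstock_table(path))
  } else {
    read_feedstock_table(path)
  }
}

#' Degradable fractions of the Weender macronutrients
#'
#' Resolves the degradable fraction of each macronutrient class for the
#' influent transformation. Protein and lipid are taken as fully degradable.
#' The carbohydrate fraction is resolved, in order of preference, from the
#' degradability quotient (DQ_XC), from acid detergent lignin
#' (\code{fd_ch = max(0, 1 - adl/xc)}; lignin treated as fully recalcitrant),
#' or from crude fibre (\code{fd_ch = max(0, 1 - alpha * xf/xc)}).
#'
#' @param spec A \code{\link{feedstock_spec}}.
#' @param xf_alpha Weight of crude fibre counted as non-degradable when the
#'   XF rule is used (default 0.5).
#' @param default_fd_ch Fallback carbohydrate degradability when the
#'   feedstock record carries no degradability information
#'   (default NULL: error).
#' @return List with components \code{fd_ch}, \code{fd_pr}, \code{fd_li},
#'   all fractions in [0, 1], and \code{rule} naming the rule applied.
#' @export
degradable_fractions <- function(spec, xf_alpha = 0.5, default_fd_ch = NULL) {
  stopifnot(inherits(spec, "feedstock_spec"))
  if (!is.na(spec$dq_xc)) {
    fd_ch <- spec$dq_xc
    rule <- "dq_xc"
  } else if (!is.na(spec$adl)) {
    fd_ch <- max(0, 1 - spec$adl / spec$xc)
    rule <- "adl"
  } else if (!is.na(spec$xf)) {
    fd_ch <- max(0, 1 - xf_alpha * spec$xf / spec$xc)
    rule <- "xf"
  } else if (!is.null(default_fd_ch)) {
    fd_ch <- default_fd_ch
    rule <- "default"
  } else {
    stop("no degradability information (dq_xc, adl or xf) for feedstock '",
         spec$name, "' and no default configured", call. = FALSE)
  }
  list(fd_ch = min(1, max(0, fd_ch)), fd_pr = 1, fd_li = 1, rule = rule)
}

#' Daily feeding schedule
#'
#' @param dates Vector of consecutive calendar dates (\code{Date} or ISO-8601
#'   strings), one per day.
#' @param feed_fm Numeric matrix or data.frame of fresh mass fed, t/d, one
#'   column per feedstock name.
#' @return An object of class \code{feed_schedule}: a data.frame with columns
#'   \code{day}, \code{date} and one fresh-mass column per feedstock.
#' @export
feed_schedule <- function(dates, feed_fm) {
  dates <- as.Date(dates)
  feed_fm <- as.data.frame(feed_fm)
  if (length(dates) != nrow(feed_fm)) {
    stop("dates and feed_fm disagree in length", call. = FALSE)
  }
  if (any(diff(as.integer(dates)) != 1L)) {
    stop("dates must be consecutive calendar days", call. = FALSE)
  }
  if (is.null(names(feed_fm)) || any(!nzchar(names(feed_fm)))) {
    stop("feed_fm columns must be named after feedstocks", call. = FALSE)
  }
  m <- as.matrix(feed_fm)
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop("feed_fm must be finite numeric", call. = FALSE)
  }
  if (any(m < 0)) stop("fresh mass fed must be >= 0", call. = FALSE)
  out <- data.frame(day = seq_along(dates), date = dates, feed_fm,
                    check.names = FALSE)
  class(out) <- c("feed_schedule", "data.frame")
  out
}

#' @export
print.feed_schedule <- function(x, ...) {
  fs <- schedule_feedstocks(x)
  cat("Feeding schedule:", nrow(x), "days (", format(x$date[1]), "to",
      format(x$date[nrow(x)]), "),", length(fs), "feedstocks\n")
  cat("  feedstocks:", paste(fs, collapse = ", "), "\n")
  cat(sprintf("  total fresh mass: mean %.1f t/d\n",
              mean(rowSums(x[, fs, drop = FALSE]))))
  invisible(x)
}

# Column names of a schedule that are feedstock feeds (not day/date).
schedule_feedstocks <- function(schedule) {
  setdiff(names(schedule), c("day", "date"))
}

#' Read a feeding-schedule table
#'
#' Comma-separated, header \code{date,<feedstock>...}, fresh t/d per cell.
#'
#' @param path Path to the CSV file.
#' @return A \code{\link{feed_schedule}}.
#' @export
read_schedule_table <- function(path) {
  if (!file.exists(path)) stop("schedule table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "date") {
    stop("schedule table must start with a 'date' column", call. = FALSE)
  }
  feed_schedule(tab$date, tab[, -1, drop = FALSE])
}

#' Transform fed fresh mass into digester influent loads
#'
#' Converts a daily feeding schedule into the mechanistic model's influent:
#' degradable carbohydrate, protein and lipid mass flows (kg/d), per-feedstock
#' and total volatile-solids flows (t VS/d), organic loading rate
#' (kg VS m^-3 d^-1) and volumetric influent flow. Per day and feedstock,
#' TS = fresh mass x ts_pct_fm/100, VS = TS x vs_pct_ts/100, and
#' x_ch = TS x xc/1000 x fd_ch (protein and lipid with fd = 1).
#'
#' @param schedule A \code{\link{feed_schedule}}.
#' @param specs A \code{feedstock_set} covering every schedule column.
#' @param config A \code{\link{digester_config}} (provides liquid volume for
#'   the OLR and HRT for the volumetric flow).
#' @param maize_name Schedule column treated as maize silage for the
#'   maize-VS feature (default \code{"maize_silage"}; NA column of zeros if
#'   absent).
#' @param xf_alpha,default_fd_ch Passed to \code{\link{degradable_fractions}}.
#' @return Class \code{influent_loads}: a data.frame with columns \code{day},
#'   \code{date}, \code{x_ch_kg_d}, \code{x_pr_kg_d}, \code{x_li_kg_d},
#'   \code{adm1_inputs_kg_d}, \code{vs_t_d}, \code{vs_maize_t_d}, \code{olr},
#'   \code{q_m3_d}; the per-feedstock VS flow matrix (t VS/d) is attached as
#'   attribute \code{"vs_by_feedstock"}.
#' @export
influent_loads <- function(schedule, specs, config,
                           maize_name = "maize_silage",
                           xf_alpha = 0.5, default_fd_ch = NULL) {
  stopifnot(inherits(schedule, "feed_schedule"))
  fs <- schedule_feedstocks(schedule)
  unknown <- setdiff(fs, names(specs))
  if (length(unknown)) {
    stop("schedule column(s) without a feedstock spec: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  fm_t <- as.matrix(schedule[, fs, drop = FALSE])      # t FM / d
  ts_kg <- sweep(fm_t * 1000, 2,
                 vapply(specs[fs], `[[`, 0, "ts_pct_fm") / 100, `*`)
  vs_kg <- sweep(ts_kg, 2, vapply(specs[fs], `[[`, 0, "vs_pct_ts") / 100, `*`)
  fd_ch <- vapply(fs, function(nm) {
    degradable_fractions(specs[[nm]], xf_alpha = xf_alpha,
                         default_fd_ch = default_fd_ch)$fd_ch
  }, 0)
  xc <- vapply(specs[fs], `[[`, 0, "xc")
  xp <- vapply(specs[fs], `[[`, 0, "xp")
  xl <- vapply(specs[fs], `[[`, 0, "xl")
  x_ch <- rowSums(sweep(ts_kg, 2, xc / 1000 * fd_ch, `*`))
  x_pr <- rowSums(sweep(ts_kg, 2, xp / 1000, `*`))
  x_li <- rowSums(sweep(ts_kg, 2, xl / 1000, `*`))
  vs_t <- vs_kg / 1000
  vs_total_t <- rowSums(vs_t)
  vs_maize <- if (maize_name %in% fs) vs_t[, maize_name] else rep(0, nrow(vs_t))
  out <- data.frame(
    day = schedule$day, date = schedule$date,
    x_ch_kg_d = x_ch, x_pr_kg_d = x_pr, x_li_kg_d = x_li,
    adm1_inputs_kg_d = x_ch + x_pr + x_li,
    vs_t_d = vs_total_t, vs_maize_t_d = vs_maize,
    olr = vs_total_t * 1000 / config$v_liq,
    q_m3_d = config$v_liq / config$hrt_d
  )
  attr(out, "vs_by_feedstock") <- vs_t
  attr(out, "fd_ch") <- fd_ch
  class(out) <- c("influent_loads", "data.frame")
  out
}
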