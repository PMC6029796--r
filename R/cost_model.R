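#' Construct the cost-analysis parameter set
#'
#' Bundles every input of the annual net-cost model: the program's staffing
#' and non-staff running costs, the equipment annualization inputs, the
#' hospital-utilisation quantities and differences, and the unit costs.
#' Utilisation parameters follow the conventional single-letter naming used
#' throughout the package:
#'
#' * `a` ED presentation rate and `b` inpatient (via ED) admission rate, both
#'   per 1,000 RACF beds per month, as expected in the catchment without the
#'   program;
#' * `c` mean ED length of stay and `d` mean inpatient length of stay, hours;
#' * `e`--`h` the program-associated differences in `a`--`d` (negative values
#'   are reductions, i.e. savings);
#' * `i` the fraction of ED presentations arriving by ambulance;
#' * `j` catchment size in *thousands* of RACF beds (so `j = 2.485` means
#'   2,485 beds), which scales the per-1,000-bed monthly quantities;
#' * `k`, `l`, `m` unit costs: AU$ per ED bed-hour, AU$ per inpatient
#'   bed-hour, AU$ per ambulance incident.
#'
#' Every field may be a vector (all non-scalar fields of a common length),
#' in which case the cost functions evaluate element-wise; this is how the
#' probabilistic sensitivity analysis propagates parameter draws.
#'
#' @param hinh_staff,in_kind annual staffing costs, AU$/yr: program nursing
#'   staff (including on-costs) and time in kind from other health
#'   professionals.
#' @param travel,admin_training,stationery,telephone,office_space annual
#'   non-staff running costs, AU$/yr.
#' @param equipment_price purchase price of program equipment, AU$.
#' @param equipment_life useful life of the equipment, years. Lives below
#'   one year are clamped to one year at annualization.
#' @param discount_rate annual discount rate used to annuitize the equipment.
#' @param a,b,c,d,e,f,g,h,i,j utilisation parameters, see Description.
#' @param k,l,m unit costs, see Description.
#' @return An object of class `hinh_parameter_set` (a named list).
#' @seealso [net_cost()], [default_parameter_set()], [run_psa()]
#' @export
parameter_set <- function(hinh_staff, in_kind,
                          travel, admin_training, stationery, telephone,
                          equipment_price, office_space,
                          equipment_life = 1, discount_rate = 0,
                          a, b, c, d, e, f, g, h, i, j, k, l, m) {
  ps <- lapply(list(hinh_staff = hinh_staff, in_kind = in_kind,
             travel = travel, admin_training = admin_training,
             stationery = stationery, telephone = telephone,
             equipment_price = equipment_price, office_space = office_space,
             equipment_life = equipment_life, discount_rate = discount_rate,
             a = a, b = b, c = c, d = d, e = e, f = f, g = g, h = h,
             i = i, j = j, k = k, l = l, m = m),
               function(x) if (is.numeric(x)) as.numeric(x) else x)
  validate_parameter_set(ps)
  structure(ps, class = "hinh_parameter_set")
}

validate_parameter_set <- function(ps) {
  lens <- lengths(ps)
  if (any(lens == 0L)) stopf("empty parameter field(s): %s",
                             paste(names(ps)[lens == 0L], collapse = ", "))
  if (length(unique(lens[lens > 1L])) > 1L)
    stopf("vector-valued parameter fields must share one length")
  for (nm in c("hinh_staff", "in_kind", "travel", "admin_training",
               "stationery", "telephone", "equipment_price", "office_space"))
    check_number(ps[[nm]], nm, lower = 0)
  check_number(ps$equipment_life, "equipment_life", lower = 0)
  check_number(ps$discount_rate, "discount_rate", lower = 0)
  for (nm in c("a", "b", "c", "d", "j", "k", "l", "m"))
    check_number(ps[[nm]], nm, lower = 0, strict_lower = TRUE)
  for (nm in c("e", "f", "g", "h")) check_number(ps[[nm]], nm)
  check_number(ps$i, "i", lower = 0, upper = 1)
  invisible(ps)
}

#' Annuity factor for an equipment life and discount rate
#'
#' `AF(L, r) = (1 - (1 + r)^-L) / r` for positive rates, with the limit `AF = L`
#' at a zero rate.
#' @param life useful life in years (non-negative).
#' @param rate annual discount rate (non-negative).
#' @return Annuity factor(s), vectorized over the inputs.
#' @export
annuity_factor <- function(life, rate) {
  check_number(life, "life", lower = 0)
  check_number(rate, "rate", lower = 0)
  n <- max(length(life), length(rate))
  life <- rep_len(life, n); rate <- rep_len(rate, n)
  ifelse(rate > 0, (1 - (1 + rate)^(-life)) / rate, life)
}

#' Equivalent annual cost of a capital purchase
#'
#' Spreads `price` over the equipment's useful life with an annuity factor.
#' Lives below one year are clamped to one year, so the degenerate
#' "bought, used for a year, discarded" case is the costliest and the
#' sensitivity-analysis range of lives starting at zero stays well defined.
#'
#' @param price purchase price, AU$.
#' @param life useful life, years.
#' @param rate annual discount rate.
#' @return AU$ per year, vectorized over the inputs.
#' @examples
#' annualize_equipment(19100, 1, 0)     # 19,100: one-year write-off
#' annualize_equipment(19100, 10, 0.05) # about 2,473.5
#' @export
annualize_equipment <- function(price, life, rate) {
  check_number(price, "price", lower = 0)
  price / annuity_factor(pmax(life, 1), rate)
}

#' Annual program costs (ledger block A)
#'
#' @param params a [parameter_set()].
#' @return List with `A1` (staffing subtotal), `A2` (non-staff subtotal,
#'   equipment annualized) and `A = A1 + A2`, AU$/yr.
#' @export
program_costs <- function(params) {
  stopifnot(inherits(params, "hinh_parameter_set"))
  A1 <- params$hinh_staff + params$in_kind
  A2 <- params$travel + params$admin_training + params$stationery +
    params$telephone + params$office_space +
    annualize_equipment(params$equipment_price, params$equipment_life,
                        params$discount_rate)
  list(A1 = A1, A2 = A2, A = A1 + A2)
}

#' Annual utilisation cost differences (ledger block B)
#'
#' Evaluates `[(e*c + a*g)*k + (f*d + b*h)*l + (e*i)*m] * j * 12` split into
#' its five components: avoided ED bed-hours (`B1a = e*c*k*j*12`), shortened
#' ED stays (`B1b = a*g*k*j*12`), avoided admissions (`B2a = f*d*l*j*12`),
#' shortened inpatient stays (`B2b = b*h*l*j*12`) and avoided ambulance
#' transports (`B3 = e*i*m*j*12`). Negative values are savings.
#'
#' @param params a [parameter_set()].
#' @return List with `B1a`, `B1b`, `B1`, `B2a`, `B2b`, `B2`, `B3`, `B`, AU$/yr.
#' @export
utilisation_costs <- function(params) {
  stopifnot(inherits(params, "hinh_parameter_set"))
  s <- params$j * 12
  B1a <- params$e * params$c * params$k * s
  B1b <- params$a * params$g * params$k * s
  B2a <- params$f * params$d * params$l * s
  B2b <- params$b * params$h * params$l * s
  B3  <- params$e * params$i * params$m * s
  list(B1a = B1a, B1b = B1b, B1 = B1a + B1b,
       B2a = B2a, B2b = B2b, B2 = B2a + B2b,
       B3 = B3, B = B1a + B1b + B2a + B2b + B3)
}

#' Annual net cost of the program (full Table-style ledger)
#'
#' Net cost `C = A + B`: program costs plus utilisation cost differences.
#' A negative `C` means the program is cost-saving over one year.
#'
#' @param params a [parameter_set()].
#' @return A `hinh_cost_breakdown`: named list with `A1`, `A2`, `A`, `B1a`,
#'   `B1b`, `B1`, `B2a`, `B2b`, `B2`, `B3`, `B`, `C` (AU$/yr), each
#'   vectorized if the parameter fields were vectors.
#' @examples
#' bd <- net_cost(default_parameter_set())
#' round(bd$C)  # negative: annual saving
#' @export
net_cost <- function(params) {
  pc <- program_costs(params)
  uc <- utilisation_costs(params)
  new_cost_breakdown(c(pc, uc))
}

new_cost_breakdown <- function(x) {
  x$C <- x$A + x$B
  structure(x[c("A1", "A2", "A", "B1a", "B1b", "B1",
                "B2a", "B2b", "B2", "B3", "B", "C")],
            class = "hinh_cost_breakdown")
}

#' Assemble a cost breakdown from its leaf components
#'
#' Computes the ledger subtotals `B1 = B1a + B1b`, `B2 = B2a + B2b`,
#' `A = A1 + A2`, `B = B1 + B2 + B3` and `C = A + B` from supplied component
#' values. Useful for checking ledger arithmetic on externally reported
#' component figures.
#'
#' @param A1,A2,B1a,B1b,B2a,B2b,B3 component values, AU$/yr.
#' @return A `hinh_cost_breakdown`.
#' @export
cost_breakdown <- function(A1, A2, B1a, B1b, B2a, B2b, B3) {
  new_cost_breakdown(list(
    A1 = A1, A2 = A2, A = A1 + A2,
    B1a = B1a, B1b = B1b, B1 = B1a + B1b,
    B2a = B2a, B2b = B2b, B2 = B2a + B2b,
    B3 = B3, B = B1a + B1b + B2a + B2b + B3))
}

#' @export
print.hinh_cost_breakdown <- function(x, ...) {
  if (length(x$C) > 1L) {
    cat(sprintf("<cost breakdown over %d parameter draws>\n", length(x$C)))
    cat(sprintf("  net cost C: mean %s, range [%s, %s]\n",
                format_aud(mean(x$C)), format_aud(min(x$C)),
                format_aud(max(x$C))))
  } else {
    writeLines(render_cost_ledger(x))
  }
  invisible(x)
}

#' Read a parameter configuration file
#'
#' Parses a JSON configuration holding the baseline [parameter_set()] and,
#' optionally, the distribution assumptions for the probabilistic
#' sensitivity analysis (see [dist_spec()]). The packaged default
#' configuration is `system.file("extdata", "hinh_parameters.json",
#' package = "hinhcost")`.
#'
#' @param path path to a JSON file.
#' @return List with elements `params` (a `hinh_parameter_set`) and `specs`
#'   (a list of `hinh_dist_spec`, possibly empty).
#' @export
read_parameter_config <- function(path) {
  if (!file.exists(path)) stopf("parameter config not found: %s", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("program_costs", "utilisation", "unit_costs")
  if (!all(need %in% names(cfg)))
    stopf("parameter config must contain blocks: %s",
          paste(need, collapse = ", "))
  pc <- cfg$program_costs
  ut <- cfg$utilisation
  un <- cfg$unit_costs
  params <- parameter_set(
    hinh_staff = pc$hinh_staff, in_kind = pc$in_kind,
    travel = pc$travel, admin_training = pc$admin_training,
    stationery = pc$stationery, telephone = pc$telephone,
    equipment_price = pc$equipment_price, office_space = pc$office_space,
    equipment_life = cfg$equipment_life %||% 1,
    discount_rate = cfg$discount_rate %||% 0,
    a = ut$a, b = ut$b, c = ut$c, d = ut$d, e = ut$e, f = ut$f,
    g = ut$g, h = ut$h, i = ut$i, j = ut$j,
    k = un$k, l = un$l, m = un$m)
  specs <- list()
  if (!is.null(cfg$distributions)) {
    dd <- cfg$distributions
    specs <- lapply(seq_len(nrow(dd)), function(r) {
      row <- as.list(dd[r, ])
      row <- row[!vapply(row, function(v) is.null(v) || all(is.na(v)),
                         logical(1))]
      do.call(dist_spec, row)
    })
  }
  list(params = params, specs = specs)
}

#' Baseline parameter set of the packaged configuration
#'
#' @return The `hinh_parameter_set` from the packaged default configuration
#'   (one-year equipment life, zero discount rate).
#' @export
default_parameter_set <- function() {
  read_parameter_config(system.file("extdata", "hinh_parameters.json",
                                    package = "hinhcost"))$params
}

#' Default distribution assumptions of the packaged configuration
#'
#' @return List of [dist_spec()] objects for every parameter varied in the
#'   probabilistic sensitivity analysis.
#' @export
default_distribution_specs <- function() {
  read_parameter_config(system.file("extdata", "hinh_parameters.json",
                                    package = "hinhcost"))$specs
}
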