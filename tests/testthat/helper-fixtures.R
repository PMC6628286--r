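# Shared fixtures, built in code at test time.

# tiny two-parameter reference used across engine tests
tiny_reference <- function() {
  df <- data.frame(parameter_name = c("A", "B"),
                   global_mean = c(10, 1),
                   global_sd = c(2, 1),
                   effect_score = c(-0.5, 0.4),
                   stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  load_parameter_reference(path)
}

# write an arbitrary data frame and return the path
write_fixture <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# two-item TEAC table: apple 15 mmol/kg, coffee 30 mmol/kg (flagged)
tiny_teac <- function() {
  load_teac_table(write_fixture(data.frame(
    item_name = c("apple", "coffee"),
    teac_content = c(15, 30),
    is_coffee = c(FALSE, TRUE))))
}

# expand a 2x2 case-control table into subject rows
# a = exposed cases, b = exposed controls, c = unexposed cases, d = unexposed controls
expand_2x2 <- function(a, b, c, d) {
  data.frame(
    case_status = rep(c(1, 0, 1, 0), times = c(a, b, c, d)),
    exposed = rep(c(1, 1, 0, 0), times = c(a, b, c, d)))
}

# small null case-control study: outcome independent of everything
null_study <- function(n, seed) {
  set.seed(seed)
  data.frame(case_status = rbinom(n, 1, 0.4),
             quartile = sample(1:4, n, replace = TRUE),
             x = rnorm(n),
             modifier = sample(c("lo", "hi"), n, replace = TRUE),
             age = rnorm(n, 60, 10))
}
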