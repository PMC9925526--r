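// Compiled kernels for the hybrid engine: a stack-machine evaluator for
// rate-law programs (RPN bytecode produced in R), the decoupled stochastic
// simulation loop, and the continuous-subnet derivative.  The R implementations
// in engine.R are the reference semantics; these kernels reproduce them (and,
// for the SSA loop, consume the R RNG stream identically, so results are
// bit-identical to the R path under the same seed).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// opcodes (keep in sync with R/rpn.R)
enum {
  OP_PUSH_CONST = 1, OP_PUSH_VAR = 2,
  OP_ADD = 3, OP_SUB = 4, OP_MUL = 5, OP_DIV = 6, OP_POW = 7, OP_NEG = 8,
  OP_EXP = 9, OP_ABS = 10, OP_FLOOR = 11, OP_CEIL = 12, OP_ROUND = 13,
  OP_MIN = 14, OP_MAX = 15
};

static double eval_prog(const int* ops, const double* args, int len,
                        const double* vars, double* stack) {
  int sp = 0;
  for (int i = 0; i < len; ++i) {
    switch (ops[i]) {
    case OP_PUSH_CONST: stack[sp++] = args[i]; break;
    case OP_PUSH_VAR:   stack[sp++] = vars[(int) args[i]]; break;
    case OP_ADD: sp--; stack[sp - 1] += stack[sp]; break;
    case OP_SUB: sp--; stack[sp - 1] -= stack[sp]; break;
    case OP_MUL: sp--; stack[sp - 1] *= stack[sp]; break;
    case OP_DIV: sp--; stack[sp - 1] /= stack[sp]; break;
    case OP_POW: sp--; stack[sp - 1] = std::pow(stack[sp - 1], stack[sp]); break;
    case OP_NEG: stack[sp - 1] = -stack[sp - 1]; break;
    case OP_EXP: stack[sp - 1] = std::exp(stack[sp - 1]); break;
    case OP_ABS: stack[sp - 1] = std::fabs(stack[sp - 1]); break;
    case OP_FLOOR: stack[sp - 1] = std::floor(stack[sp - 1]); break;
    case OP_CEIL: stack[sp - 1] = std::ceil(stack[sp - 1]); break;
    case OP_ROUND: stack[sp - 1] = ::Rf_fround(stack[sp - 1], 0.0); break;
    case OP_MIN: sp--; stack[sp - 1] = std::min(stack[sp - 1], stack[sp]); break;
    case OP_MAX: sp--; stack[sp - 1] = std::max(stack[sp - 1], stack[sp]); break;
    default: ::Rf_error("rpn: unknown opcode");
    }
  }
  return stack[0];
}

// programs in flattened form: concatenated opcode/argument arrays with
// 0-based offsets (off has k+1 entries).
// [[Rcpp::export(name = ".rpn_eval_all")]]
NumericVector rpn_eval_all(IntegerVector ops, NumericVector args,
                           IntegerVector off, NumericVector vars) {
  int k = off.size() - 1;
  NumericVector out(k);
  double stack[64];
  for (int j = 0; j < k; ++j)
    out[j] = eval_prog(ops.begin() + off[j], args.begin() + off[j],
                       off[j + 1] - off[j], vars.begin(), stack);
  return out;
}

// Continuous-subnet derivative: rates from RPN programs evaluated on the
// (clamped) state, combined through the sparse stoichiometry (si, sj, sx).
// [[Rcpp::export(name = ".rpn_ode_rhs")]]
NumericVector rpn_ode_rhs(IntegerVector ops, NumericVector args,
                          IntegerVector off, NumericVector y,
                          IntegerVector si, IntegerVector sj,
                          NumericVector sx) {
  int n = y.size();
  int k = off.size() - 1;
  std::vector<double> yc(y.begin(), y.end());
  for (int i = 0; i < n; ++i) if (yc[i] < 0) yc[i] = 0;
  double stack[64];
  NumericVector dy(n);
  std::vector<double> r(k);
  for (int j = 0; j < k; ++j)
    r[j] = eval_prog(ops.begin() + off[j], args.begin() + off[j],
                     off[j + 1] - off[j], yc.data(), stack);
  int nnz = si.size();
  for (int e = 0; e < nnz; ++e) dy[si[e]] += sx[e] * r[sj[e]];
  return dy;
}

// Decoupled stochastic phase.  All propensities depend on the discrete
// marking only; enabling uses constant-weight pre-arcs; firing deltas are
// constant.  Records the discrete marking on the output grid and the jump
// deltas applied to continuous places.  Consumes the R RNG exactly like the
// reference R loop: one exp_rand() per candidate event time, one unif_rand()
// per transition selection.
// [[Rcpp::export(name = ".ssa_decoupled")]]
List ssa_decoupled(IntegerVector ops, NumericVector args, IntegerVector off,
                   NumericVector md0,
                   IntegerVector en_t, IntegerVector en_p, NumericVector en_w,
                   List fire_di, List fire_dv, List fire_ci, List fire_cv,
                   NumericVector grid, double t_end, int n_cont) {
  RNGScope rngScope;
  int n_st = off.size() - 1;
  int n_disc = md0.size();
  int n_pts = grid.size();
  std::vector<double> md(md0.begin(), md0.end());
  NumericMatrix Mdisc(n_pts, n_disc);
  std::vector<double> jt, jv;
  std::vector<int> jp;
  std::vector<double> props(n_st);
  double stack[64];

  double t = 0.0;
  int gi = 0;
  int n_en = en_t.size();

  // pre-extract firing recipes (avoids per-event SEXP handling)
  std::vector<std::vector<int> > vdi(n_st), vci(n_st);
  std::vector<std::vector<double> > vdv(n_st), vcv(n_st);
  for (int j = 0; j < n_st; ++j) {
    IntegerVector di = fire_di[j]; NumericVector dv = fire_dv[j];
    IntegerVector ci = fire_ci[j]; NumericVector cv = fire_cv[j];
    vdi[j].assign(di.begin(), di.end()); vdv[j].assign(dv.begin(), dv.end());
    vci[j].assign(ci.begin(), ci.end()); vcv[j].assign(cv.begin(), cv.end());
  }

  for (;;) {
    // propensities with enabling mask; accumulate in extended precision to
    // match base R's sum() exactly
    long double Lacc = 0.0;
    for (int j = 0; j < n_st; ++j)
      props[j] = eval_prog(ops.begin() + off[j], args.begin() + off[j],
                           off[j + 1] - off[j], md.data(), stack);
    for (int e = 0; e < n_en; ++e)
      if (md[en_p[e]] < en_w[e] - 1e-9) props[en_t[e]] = 0.0;
    for (int j = 0; j < n_st; ++j) {
      if (props[j] < 0 || !std::isfinite(props[j]))
        ::Rf_error("negative or undefined propensity encountered");
      Lacc += props[j];
    }
    double L = (double) Lacc;
    if (L <= 0) break;
    double te = t + exp_rand() / L;
    if (te > t_end) break;
    while (gi < n_pts && grid[gi] < te) {
      for (int c = 0; c < n_disc; ++c) Mdisc(gi, c) = md[c];
      ++gi;
    }
    // pick transition: inverse-CDF walk over the propensity vector
    double u = unif_rand() * L;
    int k = 0;
    double acc = props[0];
    while (k < n_st - 1 && u > acc) acc += props[++k];
    // fire
    const std::vector<int>& di = vdi[k];
    const std::vector<double>& dv = vdv[k];
    for (size_t e = 0; e < di.size(); ++e) {
      md[di[e]] += dv[e];
      if (md[di[e]] < -1e-9) ::Rf_error("firing drove a discrete marking negative");
      md[di[e]] = ::Rf_fround(md[di[e]], 0.0);
    }
    const std::vector<int>& ci = vci[k];
    const std::vector<double>& cv = vcv[k];
    for (size_t e = 0; e < ci.size(); ++e) {
      jt.push_back(te); jp.push_back(ci[e]); jv.push_back(cv[e]);
    }
    t = te;
  }
  while (gi < n_pts) {
    for (int c = 0; c < n_disc; ++c) Mdisc(gi, c) = md[c];
    ++gi;
  }
  return List::create(_["Mdisc"] = Mdisc,
                      _["md"] = NumericVector(md.begin(), md.end()),
                      _["jt"] = NumericVector(jt.begin(), jt.end()),
                      _["jp"] = IntegerVector(jp.begin(), jp.end()),
                      _["jv"] = NumericVector(jv.begin(), jv.end()),
                      _["n_cont"] = n_cont);
}
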