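#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact solver for small 0/1 linear programs:
//   maximize  obj'x  subject to  A x {<=,>=,==} rhs,  x binary.
//
// Depth-first search in the given variable order, branching x = 1 before
// x = 0, with two prunes: (a) row-bound infeasibility, maintained
// incrementally per row as variables are fixed, and (b) an objective bound
// equal to the current value plus the positive part of the free objective.
// A new incumbent must improve strictly, so among optima the solver returns
// the one whose 1-variables come earliest in the variable order -- the tie
// rule the pair-selection model relies on.

namespace {

struct Problem {
  int nvar, nrow;
  std::vector<double> obj;
  // column-wise incidence: for var j, rows it touches and coefficients
  std::vector<std::vector<int> > colRow;
  std::vector<std::vector<double> > colVal;
  std::vector<int> dir;  // 0: <=, 1: >=, 2: ==
  std::vector<double> rhs;
};

struct State {
  std::vector<double> fixedSum, freePos, freeNeg;  // per row
  std::vector<int> x;
  double curObj, posFreeObj;
  double bestObj;
  bool haveBest;
  std::vector<int> bestX;
};

const double EPS = 1e-9;

bool rowsFeasible(const Problem& p, const State& s, const std::vector<int>& rows) {
  for (size_t t = 0; t < rows.size(); ++t) {
    int r = rows[t];
    double lo = s.fixedSum[r] + s.freeNeg[r];
    double hi = s.fixedSum[r] + s.freePos[r];
    if (p.dir[r] == 0) {               // <=
      if (lo > p.rhs[r] + EPS) return false;
    } else if (p.dir[r] == 1) {        // >=
      if (hi < p.rhs[r] - EPS) return false;
    } else {                           // ==
      if (lo > p.rhs[r] + EPS || hi < p.rhs[r] - EPS) return false;
    }
  }
  return true;
}

void search(const Problem& p, State& s, int j) {
  if (s.haveBest && s.curObj + s.posFreeObj <= s.bestObj + EPS) return;
  if (j == p.nvar) {
    // row feasibility was maintained on the way down; all vars fixed
    s.bestObj = s.curObj;
    s.bestX = s.x;
    s.haveBest = true;
    return;
  }
  const std::vector<int>& rows = p.colRow[j];
  const std::vector<double>& vals = p.colVal[j];
  double objj = p.obj[j];
  double posj = objj > 0 ? objj : 0.0;

  for (int v = 1; v >= 0; --v) {
    // fix x_j = v
    for (size_t t = 0; t < rows.size(); ++t) {
      int r = rows[t];
      double a = vals[t];
      if (a > 0) s.freePos[r] -= a; else s.freeNeg[r] -= a;
      s.fixedSum[r] += a * v;
    }
    s.posFreeObj -= posj;
    s.curObj += objj * v;
    s.x[j] = v;

    if (rowsFeasible(p, s, rows)) search(p, s, j + 1);

    // undo
    s.curObj -= objj * v;
    s.posFreeObj += posj;
    for (size_t t = 0; t < rows.size(); ++t) {
      int r = rows[t];
      double a = vals[t];
      s.fixedSum[r] -= a * v;
      if (a > 0) s.freePos[r] += a; else s.freeNeg[r] += a;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List bnb_solve(NumericVector obj, IntegerVector row_index, IntegerVector col_index,
               NumericVector value, IntegerVector dir, NumericVector rhs) {
  Problem p;
  p.nvar = obj.size();
  p.nrow = rhs.size();
  p.obj = as<std::vector<double> >(obj);
  p.dir = as<std::vector<int> >(dir);
  p.rhs = as<std::vector<double> >(rhs);
  p.colRow.assign(p.nvar, std::vector<int>());
  p.colVal.assign(p.nvar, std::vector<double>());

  State s;
  s.fixedSum.assign(p.nrow, 0.0);
  s.freePos.assign(p.nrow, 0.0);
  s.freeNeg.assign(p.nrow, 0.0);
  for (int t = 0; t < row_index.size(); ++t) {
    int r = row_index[t], c = col_index[t];
    if (r < 0 || r >= p.nrow || c < 0 || c >= p.nvar)
      stop("bnb_solve: constraint index out of range");
    double a = value[t];
    p.colRow[c].push_back(r);
    p.colVal[c].push_back(a);
    if (a > 0) s.freePos[r] += a; else s.freeNeg[r] += a;
  }
  s.x.assign(p.nvar, 0);
  s.curObj = 0.0;
  s.posFreeObj = 0.0;
  for (int j = 0; j < p.nvar; ++j) if (p.obj[j] > 0) s.posFreeObj += p.obj[j];
  s.bestObj = -std::numeric_limits<double>::infinity();
  s.haveBest = false;

  // rows with no free slack must already be consistent (e.g. empty rows)
  std::vector<int> allRows(p.nrow);
  for (int r = 0; r < p.nrow; ++r) allRows[r] = r;
  if (rowsFeasible(p, s, allRows)) search(p, s, 0);

  if (!s.haveBest) {
    return List::create(_["feasible"] = false);
  }
  return List::create(_["feasible"] = true,
                      _["objective"] = s.bestObj,
                      _["solution"] = IntegerVector(s.bestX.begin(), s.bestX.end()));
}
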