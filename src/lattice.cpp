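#include <Rcpp.h>
using namespace Rcpp;

// Fast engine for the 2D stochastic model of glycan insertion at the
// leading edge (LE). Columns discretize the cell circumference (periodic);
// rows are glycan hoops stacked outward from the founding (septal) row.
//
// Rules. The LE height profile c_j is the contiguous germ-wall height per
// column; the insertion machinery rides the membrane LE, so an insertion
// at column j always targets the local front site (c_j + 1, j) -- strands
// conform to the front (they dive into lagging columns and terminate
// against higher material). The old-wall template is imperfect: each
// front site independently carries a template gap with probability f0,
// crossed with probability ppro. A strand terminating at a gap leaves an
// exposed end defect that marks the column; re-attempts there (by later
// passing strands or fresh initiations) require repair, probability prep.
// Idle IDCs bind a uniformly random column of the LE ring and initiate
// polymerization from the glycan end there with probability prep. One
// action per IDC per tick, shuffled order; the run stops as soon as the
// mean LE height reaches the target.
//
// The single-tick reference implementation of the same rules lives in R
// (lattice_step); this engine is used for long runs and batches.

namespace {

struct Lattice {
  int M;
  double prep, ppro, f0;
  std::vector<int> c;          // LE (contiguous) height per column
  std::vector<uint8_t> marked; // column carries an exposed end defect
  std::vector<uint8_t> gap;    // template gap at the current front site
  long long csum, target;
  std::vector<int> i_row, i_col, i_dir;
  std::vector<uint8_t> i_poly;
  long long fills;

  void fill(int j) {
    ++c[j]; ++csum; ++fills;
    marked[j] = 0;
    gap[j] = (unif_rand() < f0) ? 1 : 0; // template above the new site
  }
  bool done() const { return csum >= target; }
  int wrap(int j) const { return ((j % M) + M) % M; }
};

int runif_int(int n) { // uniform on 0..n-1
  int k = (int)std::floor(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// trial to insert at the front site of column j; true when filled
bool try_insert(Lattice &L, int j) {
  double q = 1.0;
  if (L.gap[j]) q *= L.ppro;     // gap in the old-wall template
  if (L.marked[j]) q *= L.prep;  // end defect needing repair
  if (q >= 1.0 || unif_rand() < q) { L.fill(j); return true; }
  return false;
}

void idc_act(Lattice &L, int k) {
  if (L.i_poly[k]) {
    // processive circumferential motion: move one column and insert at the
    // local front site there, conforming to the front (diving into lagging
    // columns, climbing over higher material)
    int j = L.wrap(L.i_col[k] + L.i_dir[k]);
    if (try_insert(L, j)) {
      L.i_col[k] = j;
    } else {                     // terminate, leaving an end defect
      L.marked[j] = 1;
      L.i_poly[k] = 0;
    }
    return;
  }
  // idle IDC: bind a uniformly random column of the LE ring and initiate
  // polymerization from the glycan end there with probability prep
  int j0 = runif_int(L.M);
  if (unif_rand() >= L.prep) return;
  double q = 1.0;
  if (L.gap[j0]) q *= L.ppro;
  if (L.marked[j0]) q *= L.prep;
  if (q < 1.0 && unif_rand() >= q) { L.marked[j0] = 1; return; }
  L.fill(j0);
  L.i_col[k] = j0;
  L.i_dir[k] = (unif_rand() < 0.5) ? 1 : -1;
  L.i_poly[k] = 1;
}

} // namespace

// [[Rcpp::export]]
List lattice_run_cpp(int M, double prep, double ppro, int nidc, double f0,
                     int H_target, double stall_ticks) {
  Lattice L;
  L.M = M; L.prep = prep; L.ppro = ppro; L.f0 = f0;
  L.csum = 0; L.fills = 0;
  L.target = (long long)H_target * M;
  L.c.assign(M, 0);
  L.marked.assign(M, 0);
  L.gap.assign(M, 0);
  // founding row: fully occupied except a fraction f0 of holes, which are
  // exposed-end defects of the septal template
  for (int j = 0; j < M; ++j) {
    if (unif_rand() >= f0) {
      L.c[j] = 1; ++L.csum;
      L.gap[j] = (unif_rand() < f0) ? 1 : 0;
    } else {
      L.marked[j] = 1;
    }
  }
  L.i_row.assign(nidc, 0); L.i_col.assign(nidc, 0);
  L.i_dir.assign(nidc, 1); L.i_poly.assign(nidc, 0);

  std::vector<int> order(nidc);
  for (int k = 0; k < nidc; ++k) order[k] = k;

  double ticks = 0, idle_ticks = 0;
  bool stalled = false;
  while (!L.done()) {
    for (int k = nidc - 1; k > 0; --k)
      std::swap(order[k], order[runif_int(k + 1)]);
    long long before = L.fills;
    for (int k = 0; k < nidc; ++k) {
      idc_act(L, order[k]);
      if (L.done()) break;        // stop at the target mean LE height
    }
    ++ticks;
    idle_ticks = (L.fills == before) ? idle_ticks + 1 : 0;
    if (idle_ticks >= stall_ticks) { stalled = true; break; }
    if (((long long)ticks & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  IntegerVector c(L.c.begin(), L.c.end());
  int ndef = 0;
  for (int j = 0; j < M; ++j) ndef += L.marked[j];
  return List::create(
    _["h"] = c, _["ticks"] = ticks, _["fills"] = (double)L.fills,
    _["n_defects"] = ndef, _["stalled"] = stalled);
}
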