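// Spatially explicit individual-based forward simulator.
//
// Non-overlapping generations at a fixed population size N. Each offspring's
// mother is drawn with probability proportional to
//   fitness / local crowding,
// where fitness is additive in the beneficial allele (1, 1+s, 1+2s) and the
// local crowding of an individual is the population density (individuals per
// km^2) in the 3x3 neighborhood of its model grid cell -- a lightweight
// emulation of spatial competition within the interaction radius. The mate is
// drawn uniformly among individuals within the mating radius of the mother
// (exact haversine check via latitude-band spatial hashing). Offspring
// inherit one allele from each parent, and are displaced from the mother by
// an isotropic Gaussian (SD dispersal_sd_km); draws landing on water or
// outside the map are rejected and redrawn, keeping the mother's location if
// no draw lands.
//
// Randomness comes from R's RNG, so set.seed() in R makes runs reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double KM_PER_DEG = 111.19492664455873;  // 6371 km sphere

static inline double hav_km(double lat1, double lon1, double lat2,
                            double lon2) {
  const double to_rad = M_PI / 180.0;
  double dphi = (lat2 - lat1) * to_rad, dlam = (lon2 - lon1) * to_rad;
  double a = std::sin(dphi / 2) * std::sin(dphi / 2) +
             std::cos(lat1 * to_rad) * std::cos(lat2 * to_rad) *
                 std::sin(dlam / 2) * std::sin(dlam / 2);
  if (a > 1.0) a = 1.0;
  return 2.0 * 6371.0 * std::asin(std::sqrt(a));
}

struct Grid {
  int nr, nc;
  double lat_min, lon_min, res;
  const int* land;  // column-major nr x nc, 1 = land

  bool on_land(double lat, double lon) const {
    int r = (int)std::floor((lat - lat_min) / res);
    int c = (int)std::floor((lon - lon_min) / res);
    if (r < 0 || r >= nr || c < 0 || c >= nc) return false;
    return land[r + (size_t)nr * c] != 0;
  }
  int cell_of(double lat, double lon) const {
    int r = (int)std::floor((lat - lat_min) / res);
    int c = (int)std::floor((lon - lon_min) / res);
    if (r < 0) r = 0; if (r >= nr) r = nr - 1;
    if (c < 0) c = 0; if (c >= nc) c = nc - 1;
    return r + nr * c;
  }
};

// [[Rcpp::export]]
List forward_sim_cpp(int n_individuals, double s, int n_generations,
                     double origin_lat, double origin_lon,
                     IntegerMatrix land, double lat_min, double lon_min,
                     double resolution, NumericVector cell_area_by_row,
                     double mating_radius_km, double dispersal_sd_km,
                     int record_every, int burn_in, NumericVector init_at) {
  const int N = n_individuals;
  Grid grid{land.nrow(), land.ncol(), lat_min, lon_min, resolution,
            INTEGER(land)};
  const int nr = grid.nr, nc = grid.nc;

  // land cells for uniform initial placement
  std::vector<int> land_cells;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (land(r, c)) land_cells.push_back(r + nr * c);
  if (land_cells.empty()) stop("no land cells on the landscape");
  if (!grid.on_land(origin_lat, origin_lon))
    stop("forward simulation origin is not on land");

  std::vector<double> lat(N), lon(N);
  std::vector<int> g(N, 0);
  if (init_at.size() == 2) {
    // point release: all founders at one location (testing / range expansion)
    for (int i = 0; i < N; ++i) { lat[i] = init_at[0]; lon[i] = init_at[1]; }
  } else {
    for (int i = 0; i < N; ++i) {
      int cell = land_cells[(int)(unif_rand() * land_cells.size())];
      int r = cell % nr, c = cell / nr;
      lat[i] = lat_min + (r + unif_rand()) * resolution;
      lon[i] = lon_min + (c + unif_rand()) * resolution;
    }
  }

  // latitude-band hashing for mate search
  const double band_h_deg = mating_radius_km / KM_PER_DEG;
  const int n_bands = std::max(1, (int)std::ceil(nr * resolution / band_h_deg));
  std::vector<std::vector<int>> bands(n_bands);
  std::vector<std::vector<double>> band_lon(n_bands);

  // records
  std::vector<int> rec_gen, rec_geno;
  std::vector<double> rec_lat, rec_lon;
  size_t reserve = (size_t)N * (n_generations / std::max(1, record_every) + 2);
  rec_gen.reserve(reserve); rec_geno.reserve(reserve);
  rec_lat.reserve(reserve); rec_lon.reserve(reserve);

  std::vector<double> new_lat(N), new_lon(N), weight(N), cumw(N);
  std::vector<int> new_g(N), cell_count(nr * nc);
  std::vector<long> pref((size_t)(nr + 1) * (nc + 1), 0L);
  std::vector<double> area_pref(nr + 1, 0.0);
  for (int r = 0; r < nr; ++r)
    area_pref[r + 1] = area_pref[r] + cell_area_by_row[r];
  bool lost = false;
  int generation_introduced = -1;

  auto record = [&](int gen) {
    for (int i = 0; i < N; ++i) {
      rec_gen.push_back(gen); rec_geno.push_back(g[i]);
      rec_lat.push_back(lat[i]); rec_lon.push_back(lon[i]);
    }
  };

  for (int gen = 0; gen < n_generations; ++gen) {
    // introduce the beneficial allele as a single copy after burn-in
    if (gen == burn_in) {
      // carrier placed at the origin
      int carrier = (int)(unif_rand() * N);
      lat[carrier] = origin_lat;
      lon[carrier] = origin_lon;
      g[carrier] = 1;
      generation_introduced = gen;
    }
    if (gen >= burn_in && gen % std::max(1, record_every) == 0) record(gen);

    // local crowding: population density (per km^2) in the rectangle of grid
    // cells spanning the interaction radius around each individual's cell,
    // computed with 2D prefix sums
    std::fill(cell_count.begin(), cell_count.end(), 0);
    for (int i = 0; i < N; ++i) ++cell_count[grid.cell_of(lat[i], lon[i])];
    // prefix[r + (nr+1)*c] over counts; area prefix over rows
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r)
        pref[(r + 1) + (size_t)(nr + 1) * (c + 1)] =
            cell_count[r + nr * c] +
            pref[r + (size_t)(nr + 1) * (c + 1)] +
            pref[(r + 1) + (size_t)(nr + 1) * c] -
            pref[r + (size_t)(nr + 1) * c];
    const int hr = std::max(1, (int)std::ceil(
        mating_radius_km / (KM_PER_DEG * resolution)));

    // mother weights: additive fitness / local density
    double total_w = 0;
    for (int i = 0; i < N; ++i) {
      int cell = grid.cell_of(lat[i], lon[i]);
      int r = cell % nr, c = cell / nr;
      const double coslat = std::max(
          0.05, std::cos((lat_min + (r + 0.5) * resolution) * M_PI / 180.0));
      int hc = std::max(1, (int)std::ceil(
          mating_radius_km / (KM_PER_DEG * coslat * resolution)));
      int r1 = std::max(0, r - hr), r2 = std::min(nr - 1, r + hr);
      int c1 = std::max(0, c - hc), c2 = std::min(nc - 1, c + hc);
      long cnt = pref[(r2 + 1) + (size_t)(nr + 1) * (c2 + 1)] -
                 pref[r1 + (size_t)(nr + 1) * (c2 + 1)] -
                 pref[(r2 + 1) + (size_t)(nr + 1) * c1] +
                 pref[r1 + (size_t)(nr + 1) * c1];
      double area = (area_pref[r2 + 1] - area_pref[r1]) * (c2 - c1 + 1);
      double dens = std::max(1L, cnt) / std::max(area, 1e-9);
      double fit = 1.0 + s * g[i];
      weight[i] = fit / dens;
      total_w += weight[i];
      cumw[i] = total_w;
    }

    // rebuild mate-search hash
    for (int b = 0; b < n_bands; ++b) { bands[b].clear(); band_lon[b].clear(); }
    for (int i = 0; i < N; ++i) {
      int b = (int)((lat[i] - lat_min) / band_h_deg);
      if (b < 0) b = 0; if (b >= n_bands) b = n_bands - 1;
      bands[b].push_back(i);
    }

    for (int off = 0; off < N; ++off) {
      // sample mother by cumulative weight
      double u = unif_rand() * total_w;
      int mom = (int)(std::lower_bound(cumw.begin(), cumw.end(), u) -
                      cumw.begin());
      if (mom >= N) mom = N - 1;

      // mate: uniform among individuals within the mating radius
      int mb = (int)((lat[mom] - lat_min) / band_h_deg);
      if (mb < 0) mb = 0; if (mb >= n_bands) mb = n_bands - 1;
      int b_lo = std::max(0, mb - 1), b_hi = std::min(n_bands - 1, mb + 1);
      size_t pool = 0;
      for (int b = b_lo; b <= b_hi; ++b) pool += bands[b].size();
      // fathers are drawn within the mating radius with probability
      // proportional to fitness (selection acts through both parents, as in
      // viability-style fitness)
      int dad = mom;
      const double fit_cap = 1.0 + 2.0 * s;
      for (int tries = 0; tries < 90; ++tries) {
        size_t pick = (size_t)(unif_rand() * pool);
        int cand = -1;
        for (int b = b_lo; b <= b_hi; ++b) {
          if (pick < bands[b].size()) { cand = bands[b][pick]; break; }
          pick -= bands[b].size();
        }
        if (cand < 0 || cand == mom) continue;
        if (hav_km(lat[mom], lon[mom], lat[cand], lon[cand]) >
            mating_radius_km) continue;
        if (s > 0 && unif_rand() * fit_cap > 1.0 + s * g[cand]) continue;
        dad = cand;
        break;
      }

      // Mendelian inheritance, additive locus
      int allele_m = (g[mom] == 2) ? 1 : (g[mom] == 1 && unif_rand() < 0.5);
      int allele_d = (g[dad] == 2) ? 1 : (g[dad] == 1 && unif_rand() < 0.5);
      new_g[off] = allele_m + allele_d;

      // Gaussian dispersal from the mother, rejected off water/map
      double olat = lat[mom], olon = lon[mom];
      const double coslat = std::max(0.05, std::cos(lat[mom] * M_PI / 180.0));
      for (int tries = 0; tries < 100; ++tries) {
        double dlat = norm_rand() * dispersal_sd_km / KM_PER_DEG;
        double dlon = norm_rand() * dispersal_sd_km / (KM_PER_DEG * coslat);
        if (grid.on_land(lat[mom] + dlat, lon[mom] + dlon)) {
          olat = lat[mom] + dlat; olon = lon[mom] + dlon; break;
        }
      }
      new_lat[off] = olat; new_lon[off] = olon;
    }

    lat.swap(new_lat); lon.swap(new_lon); g.swap(new_g);

    if (gen >= burn_in) {
      long copies = 0;
      for (int i = 0; i < N; ++i) copies += g[i];
      if (copies == 0) {
        lost = true;
        record(gen + 1);  // final (all-ancestral) generation is still data
        break;
      }
    }
  }

  if (!lost) record(n_generations);

  return List::create(
    _["generation"] = IntegerVector(rec_gen.begin(), rec_gen.end()),
    _["lat"] = NumericVector(rec_lat.begin(), rec_lat.end()),
    _["lon"] = NumericVector(rec_lon.begin(), rec_lon.end()),
    _["genotype"] = IntegerVector(rec_geno.begin(), rec_geno.end()),
    _["lost"] = lost,
    _["generation_introduced"] = generation_introduced);
}
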