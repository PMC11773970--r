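# Frozen reference DNA/DNA nearest-neighbor Tm values, computed with an
# independent implementation of the two-state NN model (Biopython
# MeltingTemp.Tm_NN, matching parameter tables, 0.25 uM per strand).
# Conditions at 1 M Na+ use no salt correction; others use the entropic
# dS + 0.368 (N-1) ln[Na+] correction.
tm_reference_cases <- data.frame(
  seq = c(
    "GGCTCAACCCTGGACAG", "GGCTCAACCCTGGACAG", "GGCTCAACCCTGGACAG",
    "GGCTCAACCCTGGACAG", "GGCTCAACCCTGGACAG", "GGCTCAACCCTGGACAG",
    "GGCAAGTGTTCTTCGGA", "GGCAAGTGTTCTTCGGA", "GGCAAGTGTTCTTCGGA",
    "GGCAAGTGTTCTTCGGA", "GGCAAGTGTTCTTCGGA", "GGCAAGTGTTCTTCGGA",
    "GTGAATTGGTTTCGAGA", "GTGAATTGGTTTCGAGA", "GTGAATTGGTTTCGAGA",
    "GTGAATTGGTTTCGAGA", "GTGAATTGGTTTCGAGA", "GTGAATTGGTTTCGAGA",
    "GTGGAATTTCGTGTGTA", "GTGGAATTTCGTGTGTA", "GTGGAATTTCGTGTGTA",
    "GTGGAATTTCGTGTGTA", "GTGGAATTTCGTGTGTA", "GTGGAATTTCGTGTGTA",
    "GGTTGAAAGTGAAAGTC", "GGTTGAAAGTGAAAGTC", "GGTTGAAAGTGAAAGTC",
    "GGTTGAAAGTGAAAGTC", "GGTTGAAAGTGAAAGTC", "GGTTGAAAGTGAAAGTC",
    "CTAAAGACAATTACATAA", "CTAAAGACAATTACATAA", "CTAAAGACAATTACATAA",
    "CTAAAGACAATTACATAA", "CTAAAGACAATTACATAA", "CTAAAGACAATTACATAA",
    "ATACACGTCAGCACG", "ATACACGTCAGCACG", "ATACACGTCAGCACG",
    "ATACACGTCAGCACG", "ATACACGTCAGCACG", "ATACACGTCAGCACG", "AACTTGTTGGC",
    "AACTTGTTGGC", "AACTTGTTGGC", "AACTTGTTGGC", "AACTTGTTGGC",
    "AACTTGTTGGC", "CAGTGTGAATCGC", "CAGTGTGAATCGC", "CAGTGTGAATCGC",
    "CAGTGTGAATCGC", "CAGTGTGAATCGC", "CAGTGTGAATCGC",
    "TAAGGGTTAAGTAAGTGTGATGC", "TAAGGGTTAAGTAAGTGTGATGC",
    "TAAGGGTTAAGTAAGTGTGATGC", "TAAGGGTTAAGTAAGTGTGATGC",
    "TAAGGGTTAAGTAAGTGTGATGC", "TAAGGGTTAAGTAAGTGTGATGC", "TACGCCTTTAC",
    "TACGCCTTTAC", "TACGCCTTTAC", "TACGCCTTTAC", "TACGCCTTTAC",
    "TACGCCTTTAC", "TGCTGTGTCCACCCCATCGGAC", "TGCTGTGTCCACCCCATCGGAC",
    "TGCTGTGTCCACCCCATCGGAC", "TGCTGTGTCCACCCCATCGGAC",
    "TGCTGTGTCCACCCCATCGGAC", "TGCTGTGTCCACCCCATCGGAC",
    "GGCATTTTTATTACACTCAGA", "GGCATTTTTATTACACTCAGA",
    "GGCATTTTTATTACACTCAGA", "GGCATTTTTATTACACTCAGA",
    "GGCATTTTTATTACACTCAGA", "GGCATTTTTATTACACTCAGA", "ACAGAACTCGG",
    "ACAGAACTCGG", "ACAGAACTCGG", "ACAGAACTCGG", "ACAGAACTCGG",
    "ACAGAACTCGG", "TAATTTTGACAGGTCACGC", "TAATTTTGACAGGTCACGC",
    "TAATTTTGACAGGTCACGC", "TAATTTTGACAGGTCACGC", "TAATTTTGACAGGTCACGC",
    "TAATTTTGACAGGTCACGC", "AGAGGCGCGCCCTCCTGAAGTGCGT",
    "AGAGGCGCGCCCTCCTGAAGTGCGT", "AGAGGCGCGCCCTCCTGAAGTGCGT",
    "AGAGGCGCGCCCTCCTGAAGTGCGT", "AGAGGCGCGCCCTCCTGAAGTGCGT",
    "AGAGGCGCGCCCTCCTGAAGTGCGT", "GACACTCGCTATGAATCTC",
    "GACACTCGCTATGAATCTC", "GACACTCGCTATGAATCTC", "GACACTCGCTATGAATCTC",
    "GACACTCGCTATGAATCTC", "GACACTCGCTATGAATCTC", "ACGTACGTACGT",
    "ACGTACGTACGT", "ACGTACGTACGT", "ACGTACGTACGT", "ACGTACGTACGT",
    "ACGTACGTACGT"
  ),
  table = c(
    "breslauer1986", "breslauer1986", "breslauer1986", "santalucia2004",
    "santalucia2004", "santalucia2004", "breslauer1986", "breslauer1986",
    "breslauer1986", "santalucia2004", "santalucia2004", "santalucia2004",
    "breslauer1986", "breslauer1986", "breslauer1986", "santalucia2004",
    "santalucia2004", "santalucia2004", "breslauer1986", "breslauer1986",
    "breslauer1986", "santalucia2004", "santalucia2004", "santalucia2004",
    "breslauer1986", "breslauer1986", "breslauer1986", "santalucia2004",
    "santalucia2004", "santalucia2004", "breslauer1986", "breslauer1986",
    "breslauer1986", "santalucia2004", "santalucia2004", "santalucia2004",
    "breslauer1986", "breslauer1986", "breslauer1986", "santalucia2004",
    "santalucia2004", "santalucia2004", "breslauer1986", "breslauer1986",
    "breslauer1986", "santalucia2004", "santalucia2004", "santalucia2004",
    "breslauer1986", "breslauer1986", "breslauer1986", "santalucia2004",
    "santalucia2004", "santalucia2004", "breslauer1986", "breslauer1986",
    "breslauer1986", "santalucia2004", "santalucia2004", "santalucia2004",
    "breslauer1986", "breslauer1986", "breslauer1986", "santalucia2004",
    "santalucia2004", "santalucia2004", "breslauer1986", "breslauer1986",
    "breslauer1986", "santalucia2004", "santalucia2004", "santalucia2004",
    "breslauer1986", "breslauer1986", "breslauer1986", "santalucia2004",
    "santalucia2004", "santalucia2004", "breslauer1986", "breslauer1986",
    "breslauer1986", "santalucia2004", "santalucia2004", "santalucia2004",
    "breslauer1986", "breslauer1986", "breslauer1986", "santalucia2004",
    "santalucia2004", "santalucia2004", "breslauer1986", "breslauer1986",
    "breslauer1986", "santalucia2004", "santalucia2004", "santalucia2004",
    "breslauer1986", "breslauer1986", "breslauer1986", "santalucia2004",
    "santalucia2004", "santalucia2004", "breslauer1986", "santalucia2004",
    "breslauer1986", "santalucia2004", "breslauer1986", "santalucia2004"
  ),
  na_m = c(
    1.0, 0.05, 0.195, 1.0, 0.05, 0.195, 1.0, 0.05, 0.195, 1.0, 0.05, 0.195,
    1.0, 0.05, 0.195, 1.0, 0.05, 0.195, 1.0, 0.05, 0.195, 1.0, 0.05, 0.195,
    1.0, 0.05, 0.195, 1.0, 0.05, 0.195, 1.0, 0.05, 0.195, 1.0, 0.05, 0.195,
    1.0, 0.05, 0.195, 1.0, 0.05, 0.195, 1.0, 0.05, 0.195, 1.0, 0.05, 0.195,
    1.0, 0.05, 0.195, 1.0, 0.05, 0.195, 1.0, 0.05, 0.195, 1.0, 0.05, 0.195,
    1.0, 0.05, 0.195, 1.0, 0.05, 0.195, 1.0, 0.05, 0.195, 1.0, 0.05, 0.195,
    1.0, 0.05, 0.195, 1.0, 0.05, 0.195, 1.0, 0.05, 0.195, 1.0, 0.05, 0.195,
    1.0, 0.05, 0.195, 1.0, 0.05, 0.195, 1.0, 0.05, 0.195, 1.0, 0.05, 0.195,
    1.0, 0.05, 0.195, 1.0, 0.05, 0.195, 1.0, 1.0, 0.05, 0.05, 0.195, 0.195
  ),
  tm = c(
    77.762196696, 61.7193248, 68.821998173, 69.84123874, 54.766121261,
    61.44721626, 75.759436905, 59.906737871, 66.926374075, 67.086869603,
    52.258438314, 58.831618202, 69.699220253, 53.595047647, 60.719636717,
    61.577366913, 46.971009543, 53.44554483, 67.522466508, 51.198868368,
    58.416541396, 61.573053059, 47.010116407, 53.465889996, 65.084663828,
    49.064999176, 56.150579848, 60.02640406, 45.584192094, 51.987045794,
    57.669912856, 42.213378783, 49.052447265, 53.287216166, 38.690462399,
    45.156675424, 65.72685518, 49.835165635, 56.866065148, 62.663529201,
    48.545560605, 54.809416718, 47.781224937, 34.475697398, 40.381084542,
    46.60178092, 33.219333493, 39.157503648, 58.24221865, 42.865692619,
    49.670641425, 55.572956389, 42.105755364, 48.084600034, 75.94020166,
    59.238627445, 66.623741488, 68.682945986, 53.178815706, 60.044421407,
    45.580155276, 32.927366405, 38.54878415, 44.23142124, 31.058203276,
    36.904708652, 92.298799524, 74.596549858, 82.42140663, 79.552336595,
    63.716658719, 70.730954752, 72.774949205, 56.450811495, 63.671792317,
    64.25261543, 49.080744312, 55.800743451, 46.345039971, 32.473033035,
    38.622834469, 47.975729746, 34.591671308, 40.531156383, 75.02352361,
    58.748795286, 65.949801497, 66.124078789, 51.256450741, 57.846088078,
    99.051127359, 82.647446138, 89.916834313, 86.627497601, 70.56533793,
    77.681003908, 70.672341474, 53.688872838, 61.191798072, 65.07469371,
    50.392472595, 56.901495474, 48.788628871, 53.084209361, 34.916535016,
    39.633980424, 41.067553272, 45.604388199
  ),
  stringsAsFactors = FALSE
)
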