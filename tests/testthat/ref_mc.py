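# Reference marching-cubes oracle: reads a whitespace-separated file with
# the grid dims followed by the flattened (Fortran-order) label values,
# extracts the iso-0 surface with scikit-image, and prints the mesh's
# Euler characteristic, |enclosed volume| and watertightness.
import sys
import numpy as np
from skimage import measure
import trimesh

with open(sys.argv[1]) as fh:
    vals = np.array(fh.read().split(), dtype=np.float32)
d = vals[:3].astype(int)
a = vals[3:].reshape(d, order="F")
v, f, n, _ = measure.marching_cubes(a, level=0)
m = trimesh.Trimesh(v, f, process=False)
print(m.euler_number, abs(m.volume), m.is_watertight)
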