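"""Convert a single-series DICOM directory to raw float64 + JSON header.

Output raw file is little-endian float64 in Fortran (column-major) order
for an array of shape (nslice, nrow, ncol); the JSON header carries the
shape and the voxel spacing (dz, drow, dcol) in mm. Exits non-zero with a
message on mixed series, inconsistent geometry, or non-monotone slice
positions.
"""
import json
import os
import sys

import numpy as np
import pydicom


def fail(msg):
    sys.stderr.write(msg + "\n")
    sys.exit(2)


def main(dicom_dir, out_raw, out_json):
    files = sorted(
        os.path.join(dicom_dir, f)
        for f in os.listdir(dicom_dir)
        if not f.startswith(".")
    )
    slices = []
    for f in files:
        try:
            ds = pydicom.dcmread(f)
        except Exception:
            continue
        if hasattr(ds, "PixelData"):
            slices.append(ds)
    if not slices:
        fail("no DICOM images found in " + dicom_dir)

    series = {getattr(ds, "SeriesInstanceUID", "") for ds in slices}
    if len(series) > 1:
        fail("mixed DICOM series in directory")

    orients = {tuple(np.round(np.asarray(ds.ImageOrientationPatient, float), 6))
               for ds in slices if hasattr(ds, "ImageOrientationPatient")}
    if len(orients) > 1:
        fail("inconsistent image orientation across slices")
    spacings = {tuple(np.round(np.asarray(ds.PixelSpacing, float), 6))
                for ds in slices if hasattr(ds, "PixelSpacing")}
    if len(spacings) > 1:
        fail("inconsistent pixel spacing across slices")

    if orients and all(hasattr(ds, "ImagePositionPatient") for ds in slices):
        orient = np.asarray(slices[0].ImageOrientationPatient, float)
        normal = np.cross(orient[:3], orient[3:])
        pos = [float(np.dot(np.asarray(ds.ImagePositionPatient, float), normal))
               for ds in slices]
        order = np.argsort(pos)
        pos_sorted = np.asarray(pos)[order]
        if len(pos_sorted) > 1 and np.any(np.diff(pos_sorted) <= 0):
            fail("non-monotone slice positions (duplicate locations)")
        slices = [slices[i] for i in order]
        dz = float(np.median(np.diff(pos_sorted))) if len(pos_sorted) > 1 else \
            float(getattr(slices[0], "SliceThickness", 1.0))
    else:
        slices.sort(key=lambda ds: int(getattr(ds, "InstanceNumber", 0)))
        dz = float(getattr(slices[0], "SliceThickness", 1.0))

    planes = []
    for ds in slices:
        arr = ds.pixel_array.astype(np.float64)
        slope = float(getattr(ds, "RescaleSlope", 1.0))
        inter = float(getattr(ds, "RescaleIntercept", 0.0))
        planes.append(arr * slope + inter)
    shapes = {p.shape for p in planes}
    if len(shapes) > 1:
        fail("inconsistent slice dimensions")

    vol = np.stack(planes, axis=0)  # (nslice, nrow, ncol)
    if hasattr(slices[0], "PixelSpacing"):
        ps = [float(v) for v in slices[0].PixelSpacing]  # (row, col)
    else:
        ps = [1.0, 1.0]

    vol.ravel(order="F").tofile(out_raw)
    with open(out_json, "w") as fh:
        json.dump({"shape": list(vol.shape),
                   "spacing": [abs(dz), ps[0], ps[1]]}, fh)


if __name__ == "__main__":
    if len(sys.argv) != 4:
        fail("usage: dicom_to_raw.py <dicom_dir> <out_raw> <out_json>")
    main(sys.argv[1], sys.argv[2], sys.argv[3])
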