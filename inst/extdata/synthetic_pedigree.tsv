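individual_id	father_id	mother_id	sex	cohort
F00005_F			M	offspring
F00005_M			F	offspring
F00005_O1	F00005_F	F00005_M	F	gen3
F00007_F			M	offspring
F00007_M			F	offspring
F00007_O1	F00007_F	F00007_M	F	gen3
F00014_F			M	offspring
F00014_M			F	offspring
F00014_O1	F00014_F	F00014_M	M	gen3
F00015_F			M	offspring
F00015_M			F	offspring
F00015_O1	F00015_F	F00015_M	F	gen3
F00027_F			M	offspring
F00027_M			F	offspring
F00027_O1	F00027_F	F00027_M	F	gen3
F00031_F			M	offspring
F00031_M			F	offspring
F00031_O1	F00031_F	F00031_M	F	gen3
F00002_F			M	offspring
F00002_M			F	offspring
F00002_O1	F00002_F	F00002_M	M	gen3
F00002_O2	F00002_F	F00002_M	F	gen3
F00008_F			M	offspring
F00008_M			F	offspring
F00008_O1	F00008_F	F00008_M	F	gen3
F00008_O2	F00008_F	F00008_M	F	gen3
F00010_F			M	offspring
F00010_M			F	offspring
F00010_O1	F00010_F	F00010_M	F	gen3
F00010_O2	F00010_F	F00010_M	F	gen3
F00017_F			M	offspring
F00017_M			F	offspring
F00017_O1	F00017_F	F00017_M	M	gen3
F00017_O2	F00017_F	F00017_M	F	gen3
F00019_F			M	offspring
F00019_M			F	offspring
F00019_O1	F00019_F	F00019_M	M	gen3
F00019_O2	F00019_F	F00019_M	M	gen3
F00020_F			M	offspring
F00020_M			F	offspring
F00020_O1	F00020_F	F00020_M	F	gen3
F00020_O2	F00020_F	F00020_M	F	gen3
F00021_F			M	offspring
F00021_M			F	offspring
F00021_O1	F00021_F	F00021_M	F	gen3
F00021_O2	F00021_F	F00021_M	M	gen3
F00022_F			M	offspring
F00022_M			F	offspring
F00022_O1	F00022_F	F00022_M	M	gen3
F00022_O2	F00022_F	F00022_M	M	gen3
F00026_F			M	offspring
F00026_M			F	offspring
F00026_O1	F00026_F	F00026_M	M	gen3
F00026_O2	F00026_F	F00026_M	F	gen3
F00029_F			M	offspring
F00029_M			F	offspring
F00029_O1	F00029_F	F00029_M	F	gen3
F00029_O2	F00029_F	F00029_M	M	gen3
F00030_F			M	offspring
F00030_M			F	offspring
F00030_O1	F00030_F	F00030_M	M	gen3
F00030_O2	F00030_F	F00030_M	M	gen3
F00032_F			M	offspring
F00032_M			F	offspring
F00032_O1	F00032_F	F00032_M	M	gen3
F00032_O2	F00032_F	F00032_M	M	gen3
F00033_F			M	offspring
F00033_M			F	offspring
F00033_O1	F00033_F	F00033_M	M	gen3
F00033_O2	F00033_F	F00033_M	M	gen3
F00037_F			M	offspring
F00037_M			F	offspring
F00037_O1	F00037_F	F00037_M	F	gen3
F00037_O2	F00037_F	F00037_M	F	gen3
F00039_F			M	offspring
F00039_M			F	offspring
F00039_O1	F00039_F	F00039_M	F	gen3
F00039_O2	F00039_F	F00039_M	F	gen3
F00001_F			M	offspring
F00001_M			F	offspring
F00001_O1	F00001_F	F00001_M	F	gen3
F00001_O2	F00001_F	F00001_M	M	gen3
F00001_O3	F00001_F	F00001_M	F	gen3
F00003_F			M	offspring
F00003_M			F	offspring
F00003_O1	F00003_F	F00003_M	M	gen3
F00003_O2	F00003_F	F00003_M	F	gen3
F00003_O3	F00003_F	F00003_M	F	gen3
F00004_F			M	offspring
F00004_M			F	offspring
F00004_O1	F00004_F	F00004_M	F	gen3
F00004_O2	F00004_F	F00004_M	F	gen3
F00004_O3	F00004_F	F00004_M	M	gen3
F00006_F			M	offspring
F00006_M			F	offspring
F00006_O1	F00006_F	F00006_M	F	gen3
F00006_O2	F00006_F	F00006_M	F	gen3
F00006_O3	F00006_F	F00006_M	M	gen3
F00013_F			M	offspring
F00013_M			F	offspring
F00013_O1	F00013_F	F00013_M	F	gen3
F00013_O2	F00013_F	F00013_M	M	gen3
F00013_O3	F00013_F	F00013_M	M	gen3
F00016_F			M	offspring
F00016_M			F	offspring
F00016_O1	F00016_F	F00016_M	F	gen3
F00016_O2	F00016_F	F00016_M	M	gen3
F00016_O3	F00016_F	F00016_M	M	gen3
F00023_F			M	offspring
F00023_M			F	offspring
F00023_O1	F00023_F	F00023_M	M	gen3
F00023_O2	F00023_F	F00023_M	M	gen3
F00023_O3	F00023_F	F00023_M	F	gen3
F00024_F			M	offspring
F00024_M			F	offspring
F00024_O1	F00024_F	F00024_M	F	gen3
F00024_O2	F00024_F	F00024_M	M	gen3
F00024_O3	F00024_F	F00024_M	F	gen3
F00025_F			M	offspring
F00025_M			F	offspring
F00025_O1	F00025_F	F00025_M	F	gen3
F00025_O2	F00025_F	F00025_M	F	gen3
F00025_O3	F00025_F	F00025_M	M	gen3
F00028_F			M	offspring
F00028_M			F	offspring
F00028_O1	F00028_F	F00028_M	M	gen3
F00028_O2	F00028_F	F00028_M	F	gen3
F00028_O3	F00028_F	F00028_M	F	gen3
F00035_F			M	offspring
F00035_M			F	offspring
F00035_O1	F00035_F	F00035_M	F	gen3
F00035_O2	F00035_F	F00035_M	M	gen3
F00035_O3	F00035_F	F00035_M	F	gen3
F00036_F			M	offspring
F00036_M			F	offspring
F00036_O1	F00036_F	F00036_M	F	gen3
F00036_O2	F00036_F	F00036_M	F	gen3
F00036_O3	F00036_F	F00036_M	F	gen3
F00040_F			M	offspring
F00040_M			F	offspring
F00040_O1	F00040_F	F00040_M	M	gen3
F00040_O2	F00040_F	F00040_M	F	gen3
F00040_O3	F00040_F	F00040_M	M	gen3
F00009_F			M	offspring
F00009_M			F	offspring
F00009_O1	F00009_F	F00009_M	F	gen3
F00009_O2	F00009_F	F00009_M	F	gen3
F00009_O3	F00009_F	F00009_M	F	gen3
F00009_O4	F00009_F	F00009_M	M	gen3
F00011_F			M	offspring
F00011_M			F	offspring
F00011_O1	F00011_F	F00011_M	F	gen3
F00011_O2	F00011_F	F00011_M	M	gen3
F00011_O3	F00011_F	F00011_M	F	gen3
F00011_O4	F00011_F	F00011_M	M	gen3
F00018_F			M	offspring
F00018_M			F	offspring
F00018_O1	F00018_F	F00018_M	F	gen3
F00018_O2	F00018_F	F00018_M	F	gen3
F00018_O3	F00018_F	F00018_M	F	gen3
F00018_O4	F00018_F	F00018_M	F	gen3
F00012_F			M	offspring
F00012_M			F	offspring
F00012_O1	F00012_F	F00012_M	M	gen3
F00012_O2	F00012_F	F00012_M	F	gen3
F00012_O3	F00012_F	F00012_M	F	gen3
F00012_O4	F00012_F	F00012_M	M	gen3
F00012_O5	F00012_F	F00012_M	F	gen3
F00034_F			M	offspring
F00034_M			F	offspring
F00034_O1	F00034_F	F00034_M	F	gen3
F00034_O2	F00034_F	F00034_M	M	gen3
F00034_O3	F00034_F	F00034_M	F	gen3
F00034_O4	F00034_F	F00034_M	M	gen3
F00034_O5	F00034_F	F00034_M	F	gen3
F00038_F			M	offspring
F00038_M			F	offspring
F00038_O1	F00038_F	F00038_M	M	gen3
F00038_O2	F00038_F	F00038_M	F	gen3
F00038_O3	F00038_F	F00038_M	M	gen3
F00038_O4	F00038_F	F00038_M	F	gen3
F00038_O5	F00038_F	F00038_M	F	gen3
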