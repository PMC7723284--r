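"cohort","task","unit","precision","recall","f1","consistent"
"discovery","ADDvNC","LA",72.3,77.04,74.6,TRUE
"discovery","ADDvNC","RA",75,78.68,76.8,TRUE
"discovery","ADDvNC","LH",86.15,91.8,88.88,TRUE
"discovery","ADDvNC","RH",75,78.68,76.8,TRUE
"discovery","ADDvNC","LI",76.27,73.77,75,TRUE
"discovery","ADDvNC","RI",72.58,73.77,73.17,TRUE
"discovery","ADDvNC","ensemble",90.62,95.08,92.8,TRUE
"discovery","ADDvmAD","LA",86,70.49,77.47,TRUE
"discovery","ADDvmAD","RA",91.3,68.85,78.5,TRUE
"discovery","ADDvmAD","LH",92.59,81.96,86.95,TRUE
"discovery","ADDvmAD","RH",91.3,68.85,78.5,TRUE
"discovery","ADDvmAD","LI",84.78,63.93,72.89,TRUE
"discovery","ADDvmAD","RI",84.44,62.29,71.69,TRUE
"discovery","ADDvmAD","ensemble",93.1,88.52,90.75,TRUE
"discovery","ADDvaAD","LA",70.31,73.77,72,TRUE
"discovery","ADDvaAD","RA",75.8,77.04,76.42,TRUE
"discovery","ADDvaAD","LH",81.53,86.88,84.12,TRUE
"discovery","ADDvaAD","RH",75.8,77.04,76.42,TRUE
"discovery","ADDvaAD","LI",71.18,68.85,70,TRUE
"discovery","ADDvaAD","RI",62.12,67.21,64.56,TRUE
"discovery","ADDvaAD","ensemble",85.07,93.44,89.06,TRUE
"discovery","mADvaAD","LA",57.14,59.01,58.06,TRUE
"discovery","mADvaAD","RA",61.53,65.57,63.49,TRUE
"discovery","mADvaAD","LH",66.66,68.85,67.74,TRUE
"discovery","mADvaAD","RH",61.53,65.57,63.49,TRUE
"discovery","mADvaAD","LI",45.94,55.73,50.37,TRUE
"discovery","mADvaAD","RI",48.52,54.09,51.16,TRUE
"discovery","mADvaAD","ensemble",67.64,73.01,70.22,TRUE
"discovery","mADvNC","LA",65.21,73.77,69.23,TRUE
"discovery","mADvNC","RA",65.07,67.21,66.12,TRUE
"discovery","mADvNC","LH",70,80.32,74.8,TRUE
"discovery","mADvNC","RH",65.07,67.21,66.12,TRUE
"discovery","mADvNC","LI",54.05,65.57,59.25,TRUE
"discovery","mADvNC","RI",52.7,63.93,57.77,TRUE
"discovery","mADvNC","ensemble",72.97,88.52,80,TRUE
"discovery","aADvNC","LA",44,54.09,48.52,TRUE
"discovery","aADvNC","RA",41.02,52.45,46.04,TRUE
"discovery","aADvNC","LH",45.33,55.73,50,TRUE
"discovery","aADvNC","RH",41.02,52.45,46.04,TRUE
"discovery","aADvNC","LI",41.09,49.18,44.77,TRUE
"discovery","aADvNC","RI",40.25,50.81,44.92,TRUE
"discovery","aADvNC","ensemble",46.66,57.37,51.47,TRUE
"replication","ADDvNC","LA",75.72,75.92,75.82,TRUE
"replication","ADDvNC","RA",77.69,77.21,77.43,FALSE
"replication","ADDvNC","LH",89.74,89.74,89.74,TRUE
"replication","ADDvNC","RH",83.94,84.19,84.06,TRUE
"replication","ADDvNC","LI",74.17,74.45,74.29,FALSE
"replication","ADDvNC","RI",75.89,76.18,75.97,FALSE
"replication","ADDvNC","ensemble",92.78,93.88,93.25,FALSE
"replication","ADDvmAD","LA",69.61,69.8,69.62,FALSE
"replication","ADDvmAD","RA",71.81,71.81,71.81,TRUE
"replication","ADDvmAD","LH",81.28,81.51,81.36,FALSE
"replication","ADDvmAD","RH",73.13,73.05,73.06,FALSE
"replication","ADDvmAD","LI",65.74,65.62,65.64,FALSE
"replication","ADDvmAD","RI",61.25,61.31,61.23,FALSE
"replication","ADDvmAD","ensemble",85.37,85.52,85.43,TRUE
"replication","mADvNC","LA",69.46,69.61,69.53,TRUE
"replication","mADvNC","RA",71.03,71.19,71.1,TRUE
"replication","mADvNC","LH",76.64,76.88,76.75,TRUE
"replication","mADvNC","RH",69.64,69.87,69.74,TRUE
"replication","mADvNC","LI",64.32,64.2,64.22,FALSE
"replication","mADvNC","RI",61.69,61.73,61.67,FALSE
"replication","mADvNC","ensemble",80.53,81.79,80.59,FALSE
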