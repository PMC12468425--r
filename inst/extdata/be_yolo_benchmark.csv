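group,id,precision,recall,f1_reported
tuning,iou0.5_conf0.25,0.814,0.824,0.819
tuning,iou0.3_conf0.25,0.874,0.884,0.879
tuning,iou0.3_conf0.1,0.782,0.922,0.846
single,yolov5n,0.796,0.926,0.856
single,yolov9t,0.755,0.934,0.835
single,yolov10n,0.760,0.923,0.833
single,yolov11n,0.717,0.946,0.816
single,yolov12n,0.782,0.922,0.846
ensemble,11n+9t,0.743,0.957,0.836
ensemble,11n+9t+5n,0.686,0.968,0.807
ensemble,11n+9t+5n+12n,0.676,0.971,0.799
ensemble,11n+9t+5n+12n+10n,0.667,0.974,0.792
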