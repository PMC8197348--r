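metric,LR,SVM,KNN,RF,MLP
accuracy,0.840,0.853,0.813,0.827,0.836
sensitivity,0.782,0.807,0.689,0.748,0.798
specificity,0.906,0.906,0.953,0.915,0.877
precision,0.903,0.906,0.943,0.908,0.880
f1,0.838,0.853,0.796,0.820,0.837
auc,0.933,0.909,0.934,0.915,0.924
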