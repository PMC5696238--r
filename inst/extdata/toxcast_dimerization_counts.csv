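table,assay,group,active,inactive
concordance,OT_ER_ERbERb_0480,binder,15,6
concordance,OT_ER_ERbERb_0480,non_binder,0,0
concordance,OT_ER_ERbERb_1440,binder,18,3
concordance,OT_ER_ERbERb_1440,non_binder,0,0
application,OT_ER_ERbERb_0480,predicted_binder,162,1280
application,OT_ER_ERbERb_0480,predicted_non_binder,13,350
application,OT_ER_ERbERb_1440,predicted_binder,135,1304
application,OT_ER_ERbERb_1440,predicted_non_binder,15,346
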