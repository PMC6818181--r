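symbol	family	role	included	exclusion_reason
SLC4A1AP	SLC4	acid_loader	TRUE	
SLC4A2	SLC4	acid_loader	TRUE	
SLC4A3	SLC4	acid_loader	TRUE	
SLC26A6	SLC26	acid_loader	TRUE	
ATP6V0B	ATP6V	acid_loader	TRUE	
ATP6V0C	ATP6V	acid_loader	TRUE	
SLC4A4	SLC4	acid_extruder	TRUE	
SLC4A9	SLC4	acid_extruder	TRUE	
SLC9A2	SLC9	acid_extruder	TRUE	
SLC9A3	SLC9	acid_extruder	TRUE	
SLC9A4	SLC9	acid_extruder	TRUE	
SLC9A9	SLC9	acid_extruder	TRUE	
SLC26A9	SLC26	acid_extruder	TRUE	
SLC16A1	SLC16	lactate_exporter	TRUE	
SLC16A3	SLC16	lactate_exporter	TRUE	
SLC4A1	SLC4	acid_loader	FALSE	expressed in only one tissue type (kidney)
SLC4A5	SLC4	acid_extruder	FALSE	expressed in only one tissue type (thyroid)
SLC4A7	SLC4	acid_extruder	FALSE	also localized to focal adhesion sites
SLC4A8	SLC4	acid_extruder	FALSE	not expressed in any samples
SLC4A10	SLC4	acid_extruder	FALSE	not expressed in any samples
SLC4A11	SLC4	acid_extruder	FALSE	does not transport bicarbonate
SLC9A1	SLC9	acid_extruder	FALSE	localized to multiple subcellular compartments
SLC9A5	SLC9	acid_extruder	FALSE	not expressed in any samples
SLC9A6	SLC9	acid_extruder	FALSE	predominantly endosomal
SLC9A7	SLC9	acid_extruder	FALSE	localized to multiple subcellular compartments
SLC9A8	SLC9	acid_extruder	FALSE	localized only in Golgi
SLC26A3	SLC26	acid_loader	FALSE	not expressed in the majority of tissue types
SLC26A4	SLC26	acid_loader	FALSE	not expressed in the majority of tissue types
SLC26A7	SLC26	acid_extruder	FALSE	mainly a chloride channel
SLC26A11	SLC26	acid_loader	FALSE	localized to five subcellular compartments, too non-specific
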