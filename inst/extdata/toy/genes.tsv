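symbol	is_mito	is_tf
Oxt	FALSE	FALSE
Avp	FALSE	FALSE
Crh	FALSE	FALSE
G004	FALSE	FALSE
G005	FALSE	FALSE
G006	FALSE	FALSE
G007	FALSE	FALSE
G008	FALSE	FALSE
G009	FALSE	FALSE
G010	FALSE	TRUE
G011	FALSE	TRUE
G012	FALSE	FALSE
G013	FALSE	FALSE
G014	FALSE	FALSE
G015	FALSE	FALSE
G016	FALSE	FALSE
G017	FALSE	FALSE
G018	FALSE	FALSE
G019	FALSE	FALSE
G020	FALSE	FALSE
G021	FALSE	FALSE
G022	FALSE	FALSE
G023	FALSE	FALSE
G024	FALSE	FALSE
G025	FALSE	FALSE
G026	FALSE	FALSE
G027	FALSE	FALSE
G028	FALSE	FALSE
G029	FALSE	FALSE
G030	FALSE	FALSE
G031	FALSE	FALSE
G032	FALSE	FALSE
G033	FALSE	FALSE
G034	FALSE	FALSE
G035	FALSE	FALSE
G036	FALSE	FALSE
G037	FALSE	FALSE
G038	FALSE	FALSE
G039	FALSE	FALSE
G040	FALSE	FALSE
G041	FALSE	FALSE
G042	FALSE	FALSE
G043	FALSE	FALSE
G044	FALSE	FALSE
G045	FALSE	FALSE
G046	FALSE	FALSE
G047	FALSE	FALSE
G048	FALSE	FALSE
G049	FALSE	FALSE
G050	FALSE	FALSE
G051	FALSE	FALSE
G052	FALSE	FALSE
G053	FALSE	FALSE
G054	FALSE	FALSE
G055	FALSE	FALSE
G056	FALSE	FALSE
G057	FALSE	FALSE
G058	FALSE	FALSE
G059	FALSE	FALSE
G060	FALSE	FALSE
G061	FALSE	FALSE
G062	FALSE	FALSE
G063	FALSE	FALSE
G064	FALSE	FALSE
G065	FALSE	FALSE
G066	FALSE	FALSE
G067	FALSE	FALSE
G068	FALSE	FALSE
G069	FALSE	FALSE
G070	FALSE	FALSE
G071	FALSE	FALSE
G072	FALSE	FALSE
G073	FALSE	FALSE
G074	FALSE	FALSE
G075	FALSE	FALSE
G076	FALSE	FALSE
G077	FALSE	FALSE
G078	FALSE	FALSE
G079	FALSE	FALSE
G080	FALSE	FALSE
G081	FALSE	FALSE
G082	FALSE	FALSE
G083	FALSE	FALSE
G084	FALSE	FALSE
G085	FALSE	FALSE
G086	FALSE	FALSE
G087	FALSE	FALSE
G088	FALSE	FALSE
G089	FALSE	FALSE
G090	FALSE	FALSE
G091	FALSE	FALSE
G092	FALSE	FALSE
G093	FALSE	FALSE
G094	FALSE	FALSE
G095	FALSE	FALSE
mt-1	TRUE	FALSE
mt-2	TRUE	FALSE
mt-3	TRUE	FALSE
mt-4	TRUE	FALSE
mt-5	TRUE	FALSE
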